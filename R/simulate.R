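#' Configuration for the synthetic multi-species panel generator
#'
#' Bundles and validates everything the generator needs: a taxonomy with
#' per-species diploid counts, per-lineage dosages of a set of true
#' trans-acting signatures, compartments with optional cis multipliers and
#' base composition, and the variant model (neutral 1/k site frequency
#' spectrum, optional excess-heterozygosity contamination and W-to-S
#' frequency distortion mimicking GC-biased gene conversion).
#'
#' @param seed integer seed governing every random draw.
#' @param sequence_length total genome length in bases (>= 10 kb).
#' @param n_chromosomes number of equally sized chromosomes.
#' @param genera nested list: `genera$<genus>$<species>` is either a
#'   diploid count or a named vector of per-subspecies diploid counts.
#' @param lineage_dosages named list mapping species to a length-K vector
#'   of non-negative signature weights.
#' @param true_signatures K x 96 matrix, rows summing to 1, columns named
#'   by `mutation_classes(3)`.
#' @param compartments list of `list(name=, fraction=, cis=, base_freqs=)`
#'   entries; `cis` is an optional named multiplier vector over classes
#'   and `base_freqs` an optional ACGT composition for the compartment's
#'   sequence. Fractions must sum to at most 1; any remainder becomes a
#'   neutral `background` compartment.
#' @param n_snvs_per_lineage lineage-specific SNVs per species.
#' @param shared_ancestral_fraction extra shared ancestral variants, as a
#'   fraction of the lineage-specific total, planted across two genera.
#' @param sfs_model allele-frequency model; only `"neutral-1/k"`.
#' @param excess_het_fraction fraction of sites whose genotypes are packed
#'   into the maximum number of heterozygotes (HWE-filter fodder).
#' @param gbgc_shift W-to-S frequency tilt; positive values push derived
#'   G/C alleles toward higher frequencies.
#' @param cpg_enrichment per-position probability of planting a CpG
#'   dinucleotide on top of the background composition.
#' @param tile tile size in bases used to lay out compartments.
#' @return validated config list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              sequence_length = 1e6,
                              n_chromosomes = 2,
                              genera,
                              lineage_dosages,
                              true_signatures,
                              compartments,
                              n_snvs_per_lineage = 10000,
                              shared_ancestral_fraction = 0,
                              sfs_model = "neutral-1/k",
                              excess_het_fraction = 0,
                              gbgc_shift = 0,
                              cpg_enrichment = 0,
                              tile = 2000) {
  if (sequence_length < 1e4) stop("sequence_length must be >= 10 kb")
  cls <- mutation_classes(3)
  true_signatures <- as.matrix(true_signatures)
  if (ncol(true_signatures) != 96) stop("true_signatures must have 96 columns")
  if (is.null(colnames(true_signatures))) colnames(true_signatures) <- cls
  if (!identical(colnames(true_signatures), cls))
    stop("true_signatures columns must be mutation_classes(3)")
  if (any(true_signatures < 0)) stop("signatures must be non-negative")
  if (any(abs(rowSums(true_signatures) - 1) > 1e-9))
    stop("signature rows must sum to 1")
  species <- unlist(lapply(genera, names), use.names = FALSE)
  if (!all(species %in% names(lineage_dosages)))
    stop("every species needs a lineage dosage vector")
  k_true <- nrow(true_signatures)
  if (any(vapply(lineage_dosages, length, integer(1)) != k_true))
    stop("dosage vectors must have one weight per true signature")
  if (any(unlist(lineage_dosages) < 0)) stop("dosages must be non-negative")
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (sum(fr) > 1 + 1e-9) stop("compartment fractions exceed 1")
  if (any(fr <= 0)) stop("compartment fractions must be positive")
  nm <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate compartment names")
  if (sum(fr) < 1 - 1e-9 && !"background" %in% nm)
    compartments <- c(compartments,
                      list(list(name = "background",
                                fraction = 1 - sum(fr))))
  if (!sfs_model %in% "neutral-1/k") stop("unknown sfs model: ", sfs_model)
  structure(list(seed = seed, sequence_length = sequence_length,
                 n_chromosomes = n_chromosomes, genera = genera,
                 lineage_dosages = lineage_dosages,
                 true_signatures = true_signatures,
                 compartments = compartments,
                 n_snvs_per_lineage = n_snvs_per_lineage,
                 shared_ancestral_fraction = shared_ancestral_fraction,
                 sfs_model = sfs_model,
                 excess_het_fraction = excess_het_fraction,
                 gbgc_shift = gbgc_shift,
                 cpg_enrichment = cpg_enrichment, tile = tile),
            class = "simulation_config")
}

#' Draw derived-allele counts from the panel site frequency spectrum
#'
#' Under the neutral model the derived count k of 2N haplotypes has
#' probability proportional to 1/k, truncated to `1 <= k <= 2N - 1`. A
#' nonzero `shift` tilts the distribution by `exp(shift * k / 2N)`,
#' emulating the transmission advantage of gene conversion for W-to-S
#' (positive shift) and the disadvantage for S-to-W (negative shift)
#' alleles.
#'
#' @param n_haplotypes 2N, at least 2.
#' @param model frequency model label; only `"neutral-1/k"`.
#' @param n number of draws.
#' @param shift exponential frequency tilt (0 = neutral).
#' @return integer vector of derived counts.
#' @export
sfs_sample <- function(n_haplotypes, model = "neutral-1/k", n = 1,
                       shift = 0) {
  if (n_haplotypes < 2) stop("need at least two haplotypes")
  if (!model %in% "neutral-1/k") stop("unknown sfs model: ", model)
  ks <- seq_len(n_haplotypes - 1L)
  w <- (1 / ks) * exp(shift * ks / n_haplotypes)
  sample(ks, n, replace = TRUE, prob = w)
}

panel_from_genera <- function(genera) {
  rows <- list()
  for (g in names(genera)) {
    for (sp in names(genera[[g]])) {
      spec <- genera[[g]][[sp]]
      if (is.null(names(spec))) spec <- setNames(spec, sp)
      for (sub in names(spec)) {
        n <- spec[[sub]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("%s_%s_%02d", sp, sub, seq_len(n)),
          subspecies = sub, species = sp, genus = g,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# integer triplet codes 0..63 for every internal position of a chromosome;
# NA where any base is not ACGT
triplet_codes <- function(seq_chars_int) {
  base <- match(seq_chars_int, utf8ToInt("A") + c(0L, 2L, 6L, 19L)) - 1L
  n <- length(base)
  if (n < 3) return(integer(0))
  c1 <- base[1:(n - 2)]; c2 <- base[2:(n - 1)]; c3 <- base[3:n]
  16L * c1 + 4L * c2 + c3
}

# lookup tables mapping triplet code -> canonical context index (1..32) and
# strand (TRUE when the central base is already A or C)
triplet_lookup <- function() {
  ctx <- mutation_contexts(3)
  codes <- 0:63
  b <- DNA_BASES4
  trip <- paste0(b[codes %/% 16 + 1], b[codes %/% 4 %% 4 + 1],
                 b[codes %% 4 + 1])
  plus <- substr(trip, 2, 2) %in% c("A", "C")
  canon <- trip
  canon[!plus] <- revcomp(trip[!plus])
  list(ctx_id = match(canon, ctx), plus = plus, ctx = ctx)
}

#' Simulate a multi-species variant panel with known signature structure
#'
#' Generates a reference genome, compartment intervals, a variant panel
#' over the configured taxonomy, and a ground-truth record. Each
#' lineage-specific SNV's class is drawn from the lineage's signature
#' mixture, multiplied by the compartment's cis multiplier and by the
#' availability of the class's context in the compartment; its frequency
#' comes from the configured site frequency spectrum and its genotypes
#' from exact assignment of k derived haplotypes to samples. Shared
#' ancestral variants are planted across two genera: with probability 1/2
#' segregating in both, otherwise fixed-derived in one and segregating in
#' the other, so both cross-genus exclusion rules see realistic input.
#' Output is deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, writes `reference.fa`,
#'   `<compartment>.bed`, `panel.vcf`, `panel.tsv` and `truth.json`.
#' @return list with `reference` (`DNAStringSet`), `compartments` (named
#'   list of `GRanges`), `calls` (site table + genotype matrix as read
#'   back by [read_vcf_calls()]), `panel`, and `truth`.
#' @export
simulate_panel <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- panel_from_genera(config$genera)
  lut <- triplet_lookup()
  cls <- mutation_classes(3)
  cls_ctx_id <- match(class_context(cls), lut$ctx)
  cls_der <- class_derived(cls)

  chrom_len <- floor(config$sequence_length / config$n_chromosomes)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  comps <- config$compartments
  comp_names <- vapply(comps, `[[`, character(1), "name")

  # --- lay out compartments on a tiling of the genome -------------------
  tile <- config$tile
  tiles_per_chrom <- chrom_len %/% tile
  total_tiles <- tiles_per_chrom * config$n_chromosomes
  n_tiles <- floor(vapply(comps, `[[`, numeric(1), "fraction") * total_tiles)
  n_tiles[1] <- n_tiles[1] + (total_tiles - sum(n_tiles))
  assignment <- sample(rep.int(seq_along(comps), n_tiles))
  tile_chrom <- rep(chroms, each = tiles_per_chrom)
  tile_start0 <- (rep(seq_len(tiles_per_chrom), config$n_chromosomes) - 1L) *
    tile

  compartments <- list()
  for (i in seq_along(comps)) {
    sel <- assignment == i
    compartments[[comp_names[i]]] <- compartment(
      comp_names[i], tile_chrom[sel], tile_start0[sel],
      tile_start0[sel] + tile)
  }

  # --- reference sequence, tile-wise with per-compartment composition ---
  freqs <- lapply(comps, function(cp) {
    f <- cp$base_freqs
    if (is.null(f)) f <- rep(0.25, 4)
    f / sum(f)
  })
  ref_chars <- lapply(chroms, function(chr) character(chrom_len))
  names(ref_chars) <- chroms
  for (chr in chroms) {
    idx <- which(tile_chrom == chr)
    draw <- character(chrom_len)
    for (i in seq_along(idx)) {
      a <- assignment[idx[i]]
      s0 <- tile_start0[idx[i]]
      draw[(s0 + 1):(s0 + tile)] <- sample(DNA_BASES4, tile, replace = TRUE,
                                           prob = freqs[[a]])
    }
    rem <- tiles_per_chrom * tile
    if (rem < chrom_len)
      draw[(rem + 1):chrom_len] <- sample(DNA_BASES4, chrom_len - rem,
                                          replace = TRUE)
    if (config$cpg_enrichment > 0) {
      hit <- which(runif(chrom_len - 1L) < config$cpg_enrichment)
      draw[hit] <- "C"
      draw[hit + 1L] <- "G"
    }
    ref_chars[[chr]] <- draw
  }
  reference <- Biostrings::DNAStringSet(
    vapply(ref_chars, paste, character(1), collapse = ""))
  names(reference) <- chroms

  # --- candidate position pools per (compartment, context) --------------
  # positions indexed globally; context id and strand cached
  pos_chrom <- rep(chroms, each = chrom_len)
  trip <- unlist(lapply(chroms, function(chr) {
    codes <- triplet_codes(utf8ToInt(paste(ref_chars[[chr]],
                                           collapse = "")))
    c(NA_integer_, codes, NA_integer_)
  }), use.names = FALSE)
  ctx_id <- ifelse(is.na(trip), NA_integer_, lut$ctx_id[trip + 1L])
  plus <- ifelse(is.na(trip), NA, lut$plus[trip + 1L])
  pos_in_chrom <- rep(seq_len(chrom_len), config$n_chromosomes)
  pos_comp <- integer(length(ctx_id))
  tile_of_pos <- (pos_in_chrom - 1L) %/% tile + 1L
  for (chr_i in seq_along(chroms)) {
    off <- (chr_i - 1L) * chrom_len
    tl <- tile_of_pos[(off + 1):(off + chrom_len)]
    ok <- tl <= tiles_per_chrom
    pos_comp[off + which(ok)] <-
      assignment[(chr_i - 1L) * tiles_per_chrom + tl[ok]]
  }
  usable <- !is.na(ctx_id) & pos_comp > 0L
  pools <- split(which(usable),
                 list(comp = pos_comp[usable], ctx = ctx_id[usable]))
  pool_key <- function(comp_i, ctx_i) paste(comp_i, ctx_i, sep = ".")
  pool_sizes <- matrix(0L, length(comps), 32L)
  for (i in seq_along(comps)) for (j in 1:32) {
    p <- pools[[pool_key(i, j)]]
    pool_sizes[i, j] <- length(p)
  }

  # --- expected class weights per (species, compartment) ----------------
  species <- unique(panel$species)
  mix <- lapply(config$lineage_dosages[species], function(d) {
    m <- as.numeric(d %*% config$true_signatures)
    m / sum(m)
  })
  cis <- lapply(comps, function(cp) {
    v <- setNames(rep(1, 96), cls)
    if (!is.null(cp$cis)) v[names(cp$cis)] <- cp$cis
    v
  })

  # --- draw lineage-specific SNVs ---------------------------------------
  draws <- list()   # per species: matrix [compartment x class] of counts
  for (sp in species) {
    w <- matrix(0, length(comps), 96)
    for (i in seq_along(comps))
      w[i, ] <- mix[[sp]] * cis[[i]] * pool_sizes[i, cls_ctx_id]
    if (sum(w) <= 0) stop("no available context for species ", sp)
    cellp <- as.vector(w) / sum(w)
    counts <- as.vector(stats::rmultinom(1, config$n_snvs_per_lineage,
                                         cellp))
    draws[[sp]] <- matrix(counts, length(comps), 96)
  }

  # allocate positions pool-wise (without replacement across species)
  site_rows <- list()
  for (i in seq_along(comps)) for (j in 1:32) {
    need_by <- lapply(species, function(sp) {
      cl <- which(cls_ctx_id == j)
      cnt <- draws[[sp]][i, cl]
      rep(cl, cnt)
    })
    total <- sum(lengths(need_by))
    if (total == 0) next
    pool <- pools[[pool_key(i, j)]]
    if (length(pool) < total)
      stop("context ", lut$ctx[j], " exhausted in compartment ",
           comp_names[i], ": need ", total, ", have ", length(pool))
    chosen <- if (length(pool) == 1) pool else sample(pool, total)
    off <- 0L
    for (s_i in seq_along(species)) {
      cl <- need_by[[s_i]]
      if (!length(cl)) next
      p <- chosen[(off + 1):(off + length(cl))]
      off <- off + length(cl)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        gpos = p, class_id = cl, species = species[s_i],
        compartment = comp_names[i], stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)

  # derived allele in reference orientation
  der <- cls_der[sites$class_id]
  flip <- !plus[sites$gpos]
  der[flip] <- complement_base(der[flip])
  sites$chrom <- pos_chrom[sites$gpos]
  sites$pos <- pos_in_chrom[sites$gpos]
  ref_base <- mapply(function(chr, p) ref_chars[[chr]][p],
                     sites$chrom, sites$pos)
  sites$ref <- unname(ref_base)
  sites$alt <- der

  # --- frequencies and genotypes ----------------------------------------
  sp_n <- table(panel$species)[species]
  geno <- matrix(0L, nrow(sites), nrow(panel),
                 dimnames = list(NULL, panel$sample))
  anc_b <- substr(sites$ref, 1, 1)
  ws <- (anc_b %in% c("A", "T")) & (der %in% c("G", "C"))
  sw <- (anc_b %in% c("G", "C")) & (der %in% c("A", "T"))
  shift <- ifelse(ws, config$gbgc_shift, ifelse(sw, -config$gbgc_shift, 0))
  sites$k <- NA_integer_
  sites$n_hap <- NA_integer_
  for (sp in species) {
    rows <- which(sites$species == sp)
    n2 <- 2L * as.integer(sp_n[[sp]])
    cols <- which(panel$species == sp)
    k <- integer(length(rows))
    for (s in unique(shift[rows])) {
      sel <- shift[rows] == s
      k[sel] <- sfs_sample(n2, config$sfs_model, sum(sel), shift = s)
    }
    excess <- runif(length(rows)) < config$excess_het_fraction
    for (ii in seq_along(rows)) {
      copies <- if (excess[ii]) {
        pack_excess_het(k[ii], length(cols))
      } else {
        tabulate((sample.int(n2, k[ii]) + 1L) %/% 2L, nbins = length(cols))
      }
      geno[rows[ii], cols] <- as.integer(copies)
    }
    sites$k[rows] <- k
    sites$n_hap[rows] <- n2
  }

  # --- shared ancestral variants -----------------------------------------
  n_shared <- round(config$shared_ancestral_fraction *
                      config$n_snvs_per_lineage * length(species))
  genera_names <- unique(panel$genus)
  if (n_shared > 0 && length(genera_names) < 2)
    stop("shared ancestral variants need at least two genera")
  if (n_shared > 0) {
    remaining <- setdiff(which(usable), sites$gpos)
    if (length(remaining) < n_shared)
      stop("not enough free positions for shared ancestral variants")
    p <- sample(remaining, n_shared)
    avg_mix <- Reduce(`+`, mix) / length(mix)
    # class by the average lineage mixture, conditioned on each position's
    # available context
    cond <- vapply(p, function(gp) {
      cl <- which(cls_ctx_id == ctx_id[gp])
      cl[sample.int(3L, 1L, prob = avg_mix[cl])]
    }, integer(1))
    der_s <- cls_der[cond]
    fl <- !plus[p]
    der_s[fl] <- complement_base(der_s[fl])
    sh <- data.frame(gpos = p, class_id = cond, species = "shared",
                     compartment = comp_names[pos_comp[p]],
                     chrom = pos_chrom[p], pos = pos_in_chrom[p],
                     ref = vapply(seq_along(p), function(i)
                       ref_chars[[pos_chrom[p[i]]]][pos_in_chrom[p[i]]],
                       character(1)),
                     alt = der_s, k = NA_integer_, n_hap = NA_integer_,
                     stringsAsFactors = FALSE)
    geno_s <- matrix(0L, n_shared, nrow(panel),
                     dimnames = list(NULL, panel$sample))
    g_pair <- t(vapply(seq_len(n_shared), function(i)
      sample(genera_names, 2L), character(2)))
    seg_both <- runif(n_shared) < 0.5
    seg_geno <- function(cols) {
      n2 <- 2L * length(cols)
      kk <- sfs_sample(n2, config$sfs_model, 1)
      as.integer(tabulate((sample.int(n2, kk) + 1L) %/% 2L,
                          nbins = length(cols)))
    }
    for (i in seq_len(n_shared)) {
      c1 <- which(panel$genus == g_pair[i, 1])
      c2 <- which(panel$genus == g_pair[i, 2])
      if (seg_both[i]) {
        # segregating in two genera -> multi-genus exclusion downstream
        geno_s[i, c1] <- seg_geno(c1)
        geno_s[i, c2] <- seg_geno(c2)
      } else {
        # fixed derived in one genus, segregating in the other; with a
        # third genus present this trips the multiple-fixed-allele rule
        geno_s[i, c1] <- 2L
        geno_s[i, c2] <- seg_geno(c2)
      }
    }
    sites <- rbind(sites, sh)
    geno <- rbind(geno, geno_s)
  }

  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  rownames(sites) <- NULL

  truth <- list(
    snvs = data.frame(chrom = sites$chrom, pos = sites$pos,
                      class = cls[sites$class_id], lineage = sites$species,
                      compartment = sites$compartment, k = sites$k,
                      n_hap = sites$n_hap, stringsAsFactors = FALSE),
    expected_spectra = expected_lineage_spectra(mix, cis, pool_sizes,
                                                cls, cls_ctx_id),
    cis_multipliers = setNames(cis, comp_names),
    seed = config$seed)

  calls <- list(sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                   ref = sites$ref, alt = sites$alt,
                                   multiallelic = FALSE,
                                   stringsAsFactors = FALSE),
                geno = geno, samples = panel$sample)
  out <- list(reference = reference, compartments = compartments,
              calls = calls, panel = panel, truth = truth,
              config = config)
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

# genotype packing that maximizes heterozygotes for a given derived count
pack_excess_het <- function(k, n_ind) {
  copies <- integer(n_ind)
  n_het <- min(k, n_ind)
  if (n_het > 0) copies[seq_len(n_het)] <- 1L
  extra <- k - n_het
  if (extra > 0) copies[seq_len(extra)] <- 2L
  sample(copies)
}

expected_lineage_spectra <- function(mix, cis, pool_sizes, cls,
                                     cls_ctx_id) {
  out <- list()
  for (sp in names(mix)) {
    w <- rep(0, 96)
    for (i in seq_along(cis))
      w <- w + mix[[sp]] * cis[[i]] * pool_sizes[i, cls_ctx_id]
    out[[sp]] <- setNames(w / sum(w), cls)
  }
  out
}

write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference, file.path(dir, "reference.fa"))
  for (nm in names(sim$compartments))
    write_bed(sim$compartments[[nm]], file.path(dir, paste0(nm, ".bed")))
  write_vcf(sim$calls, sim$reference, file.path(dir, "panel.vcf"))
  utils::write.table(sim$panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Write a GT-only VCF v4.2
#'
#' @param calls call set (`sites`, `geno`, `samples`).
#' @param reference `DNAStringSet` (used for contig header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, reference, path) {
  gt <- matrix("./.", nrow(calls$geno), ncol(calls$geno))
  gt[calls$geno == 0L] <- "0/0"
  gt[calls$geno == 1L] <- "0/1"
  gt[calls$geno == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(reference),
                      Biostrings::width(reference)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", calls$samples),
                    collapse = "\t"))
  body <- paste(calls$sites$chrom, calls$sites$pos, ".", calls$sites$ref,
                calls$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
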