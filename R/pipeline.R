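#' Run the end-to-end compartment spectrum pipeline
#'
#' Orchestrates simulate (or load) -> polarize/filter -> spectra ->
#' content normalization -> PCA / NMF / distances / log-odds heatmaps
#' from one configuration, writing every stage artifact plus a manifest
#' with checksums into the output directory. Deterministic given the seed
#' and inputs.
#'
#' @param config a list with either `simulation` (a
#'   [simulation_config()]) or input paths (`vcf`, `fasta`, `panel`,
#'   `compartment_beds`, a named character vector), plus: `outdir`;
#'   `seed`; `mode` (`"full"`, `"randomized"` or `"doubletons"`);
#'   `reference_compartment` (content baseline, default the first
#'   compartment); `heatmap_pair` (two compartment names, optional);
#'   `k` and `restarts` for the NMF stage; `stages`, a character subset
#'   of `c("spectra", "normalize", "pca", "nmf", "distances",
#'   "heatmap")` (all by default).
#' @return manifest list (also written as `manifest.json`): per-stage
#'   artifact paths with md5 checksums and the resolved configuration.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else config$seed
  mode <- if (is.null(config$mode)) "randomized" else config$mode
  mode <- match.arg(mode, c("full", "randomized", "doubletons"))
  stages <- if (is.null(config$stages))
    c("spectra", "normalize", "pca", "nmf", "distances", "heatmap")
  else config$stages
  artifacts <- character(0)
  note <- function(path) artifacts <<- c(artifacts, path)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    simdir <- file.path(outdir, "simulated")
    sim <- simulate_panel(config$simulation, dir = simdir)
    note(list.files(simdir, full.names = TRUE))
    reference <- sim$reference
    compartments <- sim$compartments
    calls <- sim$calls
    panel <- sim$panel
  } else {
    reference <- Biostrings::readDNAStringSet(config$fasta)
    names(reference) <- sub("\\s.*$", "", names(reference))
    calls <- read_vcf_calls(config$vcf)
    panel <- read_panel(config$panel)
    compartments <- lapply(names(config$compartment_beds), function(nm)
      read_bed(config$compartment_beds[[nm]], name = nm))
    names(compartments) <- names(config$compartment_beds)
  }
  ref_comp <- config$reference_compartment
  if (is.null(ref_comp)) ref_comp <- names(compartments)[1]
  if (!ref_comp %in% names(compartments))
    stop("reference compartment not found: ", ref_comp)

  # --- filter --------------------------------------------------------------
  flt <- filter_sites(calls, panel, reference,
                      doubletons_only = mode == "doubletons")
  disp <- file.path(outdir, "site_dispositions.tsv")
  utils::write.table(flt$disposition, disp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note(disp)
  tally <- as.list(flt$tally)
  message("site filter tally: ",
          paste(names(tally), unlist(tally), sep = "=", collapse = ", "))

  results <- list(filter_tally = tally)
  contents <- lapply(compartments, function(cp)
    compartment_content(reference, cp, 3))
  species <- unique(panel$species)

  spectra <- list()    # rescaled rates, one entry per sample x compartment
  raw_counts <- list()
  if (any(c("spectra", "normalize", "pca", "nmf") %in% stages)) {
    for (nm in names(compartments)) {
      sub <- sites_in_compartment(flt, compartments[[nm]])
      counts <- switch(mode,
        randomized = randomized_spectrum(sub, seed = seed),
        full = ,
        doubletons = t(vapply(panel$sample, function(s)
          individual_spectrum(sub, s), empty_spectrum(3))))
      rownames(counts) <- panel$sample
      raw_counts[[nm]] <- counts
      if ("spectra" %in% stages) {
        sp_path <- file.path(outdir, paste0("spectra_", nm, ".tsv"))
        write_spectra(counts, sp_path,
                      meta = list(compartment = nm, mode = mode,
                                  seed = seed, unit = "count"))
        note(c(sp_path, paste0(sp_path, ".json")))
      }
      for (s in panel$sample) {
        if (sum(counts[s, ]) == 0) next
        spectra[[paste(s, nm, sep = "|")]] <-
          rescale_rates(counts[s, ], contents[[nm]], contents[[ref_comp]])
      }
    }
  }

  if (any(c("normalize", "pca", "nmf") %in% stages) && length(spectra)) {
    mat <- build_spectrum_matrix(spectra)
    if ("normalize" %in% stages) {
      rt <- file.path(outdir, "rescaled_rates.tsv")
      write_spectra(mat, rt, meta = list(reference = ref_comp,
                                         mode = mode, seed = seed,
                                         unit = "rate"))
      note(c(rt, paste0(rt, ".json")))
    }
    prov <- do.call(rbind, strsplit(rownames(mat), "|", fixed = TRUE))
    if ("pca" %in% stages && nrow(mat) >= 2) {
      pca <- run_pca(mat)
      results$pca <- pca
      sc <- file.path(outdir, "pca_scores.tsv")
      utils::write.table(
        data.frame(sample = prov[, 1], compartment = prov[, 2],
                   pca$scores, check.names = FALSE),
        sc, sep = "\t", quote = FALSE, row.names = FALSE)
      ld <- file.path(outdir, "pca_loadings.tsv")
      utils::write.table(
        data.frame(class = rownames(pca$loadings), pca$loadings,
                   check.names = FALSE),
        ld, sep = "\t", quote = FALSE, row.names = FALSE)
      note(c(sc, ld))
    }
    if ("nmf" %in% stages) {
      k <- if (is.null(config$k)) 6L else config$k
      restarts <- if (is.null(config$restarts)) 20L else config$restarts
      nmf <- run_nmf(mat, k = k, restarts = restarts, seed = seed)
      results$nmf <- nmf
      sg <- file.path(outdir, "nmf_signatures.tsv")
      write_spectra(nmf$signatures, sg,
                    meta = list(k = k, restarts = restarts, seed = seed))
      ex <- file.path(outdir, "nmf_exposures.tsv")
      utils::write.table(
        data.frame(row = rownames(nmf$exposures), nmf$exposures),
        ex, sep = "\t", quote = FALSE, row.names = FALSE)
      note(c(sg, paste0(sg, ".json"), ex))
    }
  }

  if ("distances" %in% stages) {
    sub <- sites_in_compartment(flt, compartments[[ref_comp]])
    counts <- if (!is.null(raw_counts[[ref_comp]]))
      raw_counts[[ref_comp]]
    else randomized_spectrum(sub, seed = seed)
    keep <- rowSums(counts) > 0
    dd <- pairwise_distance_distributions(
      counts[keep, , drop = FALSE],
      panel$species[match(rownames(counts)[keep], panel$sample)])
    results$distances <- dd
    dp <- file.path(outdir, "euclidean_distances.tsv")
    utils::write.table(dd, dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(dp)
  }

  if ("heatmap" %in% stages && !is.null(config$heatmap_pair)) {
    pair <- config$heatmap_pair
    lo <- lapply(species, function(s) {
      cnt <- lapply(pair, function(nm)
        species_spectrum(sites_in_compartment(flt, compartments[[nm]]),
                         panel, s))
      log_odds_heatmap(
        rescale_rates(cnt[[1]], contents[[pair[1]]], contents[[ref_comp]]),
        rescale_rates(cnt[[2]], contents[[pair[2]]], contents[[ref_comp]]))
    })
    names(lo) <- species
    results$log_odds <- lo
    hp <- file.path(outdir, "log_odds_heatmap.tsv")
    utils::write.table(
      data.frame(class = mutation_classes(3), do.call(cbind, lo),
                 check.names = FALSE),
      hp, sep = "\t", quote = FALSE, row.names = FALSE)
    note(hp)
  }

  artifacts <- unique(unlist(artifacts))
  manifest <- list(
    seed = seed, mode = mode, stages = stages,
    reference_compartment = ref_comp,
    filter_tally = tally,
    files = lapply(artifacts, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
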