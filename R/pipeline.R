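#' Run the contact-analysis pipeline end to end
#'
#' Orchestrates the stages — filter, matrix, normalize, stats, transloc,
#' network — in dependency order, writing plain-text TSV artifacts to
#' `out_dir` and returning a manifest of everything produced. Given the
#' same config (and seed, when inputs are simulated) a rerun reproduces
#' byte-identical outputs.
#'
#' The config is a named list (or path to a YAML file with the same
#' structure):
#'
#' * `out_dir`: output directory (created if needed).
#' * `stages`: subset of `c("filter", "matrix", "normalize", "stats",
#'   "transloc", "network")`; defaults to all. Later stages pull in what
#'   they need from earlier ones.
#' * `simulate`: arguments for [sim_params()] (a synthetic genome and read
#'   pairs are generated), **or** `inputs`: list with paths `pairs`,
#'   `genome` and optionally `features`.
#' * `filter`: arguments for [filter_pairs()] (`strategy`,
#'   `min_separation`, `insert_length`, `dedup`).
#' * `matrix`: `resolution` (default 1e6) and optional `cap`.
#' * `normalize`: `euclid_threshold` (default 10), `method`
#'   (`"scn"`, `"dist_scn"`, `"x_over_avg"`, `"minmax"`, `"zscore"`).
#' * `stats`: logical flags `correlation`, `significance`, `oe`
#'   (all default `TRUE`).
#' * `transloc`: `chrom_a`, `chrom_b`, plus optional `resolutions`,
#'   `enrichment_min`.
#' * `network`: `node_kinds` (default `"GENE"`), `threshold` (default 0).
#'
#' @param config Named list or path to a YAML config file.
#' @return A manifest tibble (`stage`, `file`, `md5`), invisibly also
#'   attached to the written `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% abort("config$out_dir is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("filter", "matrix", "normalize", "stats", "transloc",
                  "network")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]

  manifest <- list()
  emit <- function(stage, path) {
    checksum <- unname(tools::md5sum(path))
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, file = basename(path), md5 = checksum
    )
  }

  # ---- inputs ---------------------------------------------------------
  features <- NULL
  if (!is.null(config$simulate)) {
    params <- do.call(sim_params, config$simulate)
    sim <- simulate_genome(params)
    genome <- sim$genome
    features <- sim$features
    pairs <- simulate_pairs(genome, params)
    gf <- file.path(out_dir, "genome.tsv")
    readr::write_tsv(genome, gf, col_names = FALSE, progress = FALSE)
    ff <- file.path(out_dir, "features.tsv")
    readr::write_tsv(features, ff, col_names = FALSE, progress = FALSE)
    pf <- file.path(out_dir, "pairs.tsv")
    write_pairs(pairs, pf)
    emit("input", gf); emit("input", ff); emit("input", pf)
  } else if (!is.null(config$inputs)) {
    if (is.null(config$inputs$pairs) || is.null(config$inputs$genome)) {
      abort("config$inputs needs `pairs` and `genome` paths.")
    }
    genome <- read_genome(config$inputs$genome)
    pairs <- read_pairs(config$inputs$pairs)
    if (!is.null(config$inputs$features)) {
      features <- read_features(config$inputs$features)
    }
  } else {
    abort("config needs either `simulate` or `inputs`.")
  }

  # ---- filter ---------------------------------------------------------
  fargs <- config$filter %||% list()
  contacts <- filter_pairs(
    pairs, genome,
    strategy = fargs$strategy %||% "strict_unique",
    min_separation = fargs$min_separation %||% 2000,
    insert_length = fargs$insert_length %||% 2000,
    dedup = isTRUE(fargs$dedup)
  )
  if ("filter" %in% stages) {
    cf <- file.path(out_dir, "contacts.tsv")
    write_contacts(contacts, cf)
    sf <- file.path(out_dir, "filter_stats.tsv")
    readr::write_tsv(filter_stats(contacts), sf, progress = FALSE)
    emit("filter", cf); emit("filter", sf)
  }

  # ---- matrices -------------------------------------------------------
  res <- (config$matrix %||% list())$resolution %||% 1e6
  need_matrix <- any(c("matrix", "normalize", "stats") %in% stages)
  intra <- list()
  if (need_matrix) {
    for (ch in genome$chrom) {
      intra[[ch]] <- bin_contacts(contacts, genome, res, ch)
      if ("matrix" %in% stages) {
        mf <- file.path(out_dir, paste0("matrix_", ch, ".tsv"))
        write_matrix_tsv(intra[[ch]], mf)
        emit("matrix", mf)
      }
    }
    if ("matrix" %in% stages && nrow(genome) >= 2) {
      cp <- utils::combn(genome$chrom, 2)
      for (k in seq_len(ncol(cp))) {
        m <- bin_contacts(contacts, genome, res, cp[1, k], cp[2, k])
        mf <- file.path(out_dir,
                        paste0("matrix_", cp[1, k], "_", cp[2, k], ".tsv"))
        write_matrix_tsv(m, mf)
        emit("matrix", mf)
      }
    }
  }

  # ---- normalization --------------------------------------------------
  normalized <- list()
  if (any(c("normalize", "stats") %in% stages)) {
    nargs <- config$normalize %||% list()
    thr <- nargs$euclid_threshold %||% 10
    method <- nargs$method %||% "scn"
    for (ch in names(intra)) {
      m <- filter_low_coverage_bins(intra[[ch]], thr)
      m <- switch(method,
        scn = scn_normalize(m),
        dist_scn = scn_normalize(distance_normalize(m)),
        simple_normalize(m, method)
      )
      normalized[[ch]] <- m
      if ("normalize" %in% stages) {
        nf <- file.path(out_dir, paste0("normalized_", ch, ".tsv"))
        write_matrix_tsv(m, nf)
        emit("normalize", nf)
      }
    }
  }

  # ---- statistics -----------------------------------------------------
  if ("stats" %in% stages) {
    sargs <- config$stats %||% list()
    for (ch in names(intra)) {
      if (!isFALSE(sargs$correlation)) {
        cm <- correlation_matrix(normalized[[ch]])
        cfp <- file.path(out_dir, paste0("correlation_", ch, ".tsv"))
        write_matrix_tsv(cm, cfp)
        emit("stats", cfp)
      }
      if (!isFALSE(sargs$significance)) {
        sm <- poisson_significance(intra[[ch]])
        sfp <- file.path(out_dir, paste0("significance_", ch, ".tsv"))
        write_matrix_tsv(sm, sfp)
        emit("stats", sfp)
      }
    }
    if (!isFALSE(sargs$oe) && nrow(genome) >= 2) {
      counts <- inter_pair_counts(contacts)
      if (nrow(counts) > 0) {
        oe <- observed_expected_ratios(counts)
        of <- file.path(out_dir, "observed_expected.tsv")
        readr::write_tsv(oe, of, progress = FALSE)
        emit("stats", of)
      }
    }
  }

  # ---- translocation --------------------------------------------------
  if ("transloc" %in% stages) {
    targs <- config$transloc %||% list()
    ta <- targs$chrom_a %||% genome$chrom[[1]]
    tb <- targs$chrom_b %||% genome$chrom[[2]]
    model <- detect_translocation(
      contacts, genome, ta, tb,
      resolutions = unlist(targs$resolutions %||% c(1e6, 1e5, 1e4)),
      enrichment_min = targs$enrichment_min %||% 5
    )
    tf <- file.path(out_dir, "translocation.tsv")
    if (is.null(model)) {
      readr::write_tsv(
        tibble(chrom_a = character(), breakpoint_a = double(),
               chrom_b = character(), breakpoint_b = double(),
               orientation = character(), score = double()),
        tf, progress = FALSE
      )
    } else {
      readr::write_tsv(as_tibble(model), tf, progress = FALSE)
      m_inter <- bin_contacts(contacts, genome, model$resolution, ta, tb)
      part <- partition_regions(m_inter, model)
      corrected <- reconstruct_corrected_matrix(m_inter, part)
      cf2 <- file.path(out_dir, "corrected_inter.tsv")
      write_matrix_tsv(corrected, cf2)
      emit("transloc", cf2)
    }
    emit("transloc", tf)
  }

  # ---- networks -------------------------------------------------------
  if ("network" %in% stages) {
    if (is.null(features)) {
      abort("network stage requires feature annotations (simulate or inputs$features).")
    }
    nargs2 <- config$network %||% list()
    counts <- map_contacts_to_features(
      contacts, features, node_kinds = unlist(nargs2$node_kinds %||% "GENE")
    )
    net <- build_network(counts, threshold = nargs2$threshold %||% 0)
    ef <- file.path(out_dir, "network_edges.tsv")
    nf2 <- file.path(out_dir, "network_nodes.tsv")
    write_network(net, ef, nf2)
    emit("network", ef); emit("network", nf2)
  }

  manifest <- dplyr::bind_rows(manifest)
  mf <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, mf, progress = FALSE)
  manifest
}
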