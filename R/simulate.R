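#' Simulation parameters for synthetic Hi-C data
#'
#' Bundles the knobs of the synthetic-data generator. The defaults describe
#' a desk-scale two-chromosome genome whose read pairs reproduce the
#' statistical structure the pipeline assumes: power-law distance decay of
#' intra-chromosomal contact frequency, a two-compartment plaid modulation,
#' a uniform inter-chromosomal background, multi-mapping and
#' short-separation artifacts at fixed planted rates, and optionally a
#' reciprocal translocation.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_pairs Number of read pairs to draw.
#' @param alpha Distance-decay exponent: intra contact rate proportional to
#'   `d^-alpha`.
#' @param min_distance Smallest intra separation (bp) drawn from the decay
#'   law; artifact pairs below this come from `short_pair_frac`.
#' @param inter_frac Probability that a (non-artifact) pair is
#'   inter-chromosomal.
#' @param compartment_resolution Compartment-label bin size in bp.
#' @param compartment_mean_blocks Mean length, in compartment bins, of the
#'   alternating A/B blocks (geometric lengths).
#' @param plaid Plaid strength in `[0, 1)`: same-compartment pairs are
#'   accepted with probability proportional to `1 + plaid`, cross-compartment
#'   with `1 - plaid`.
#' @param multi_map_frac Fraction of records given 1–2 decoy candidate
#'   locations on one end (exact planted count `round(frac * n_pairs)`).
#' @param short_pair_frac Fraction of records given an intra separation
#'   below `min_distance` (exact planted count).
#' @param read_length Read length in bp.
#' @param n_genes,n_tfbs Total numbers of gene-like and TFBS features.
#' @param gene_length,tfbs_length Length ranges (bp) for the two feature
#'   sets.
#' @param translocation Optional `list(chrom_a, breakpoint_a, chrom_b,
#'   breakpoint_b)`: exchange the two chromosome tails at the breakpoints
#'   and draw pairs on the derivative chromosomes.
#' @param seed Master seed; every stochastic component derives its own
#'   stream from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(chrom_lengths = c(chrA = 5e6, chrB = 5e6),
                       n_pairs = 200000,
                       alpha = 1,
                       min_distance = 2000,
                       inter_frac = 0.03,
                       compartment_resolution = 100000,
                       compartment_mean_blocks = 5,
                       plaid = 0.6,
                       multi_map_frac = 0.1,
                       short_pair_frac = 0.1,
                       read_length = 100L,
                       n_genes = 50,
                       n_tfbs = 100,
                       gene_length = c(10000, 40000),
                       tfbs_length = c(200, 1000),
                       translocation = NULL,
                       seed = 1) {
  stopifnot(alpha > 0, plaid >= 0, plaid < 1,
            multi_map_frac >= 0, multi_map_frac <= 1,
            short_pair_frac >= 0, short_pair_frac <= 1,
            multi_map_frac + short_pair_frac <= 1,
            inter_frac >= 0, inter_frac <= 1,
            all(chrom_lengths > 0), n_pairs >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a genome and feature annotation
#'
#' Builds the chromosome-length table and a feature annotation containing
#' non-overlapping gene-like intervals — kinds drawn from `GENE`, `PSEUDO`,
#' `RNA`, `CDS`, `UTR` so that kind filtering is exercised downstream — and
#' a separate set of non-overlapping TFBS intervals. Deterministic given
#' the seed.
#'
#' @param params A [sim_params()] object.
#' @return List with `genome` (tibble `chrom`, `length`) and `features`
#'   (tibble `id`, `chrom`, `start`, `end`, `kind`).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  genome <- tibble(chrom = names(params$chrom_lengths),
                   length = unname(params$chrom_lengths))
  place <- function(n_total, len_range, kinds, kind_probs, prefix, stream) {
    n_per <- round(n_total * genome$length / sum(genome$length))
    # keep the requested total despite rounding
    n_per[1] <- n_per[1] + (n_total - sum(n_per))
    with_seed(substream_seed(params$seed, stream), {
      out <- purrr::map2(genome$chrom, seq_along(genome$chrom), function(ch, ci) {
        n <- n_per[ci]
        if (n <= 0) return(NULL)
        len_chr <- genome$length[ci]
        slot <- floor(len_chr / n)
        max_len <- min(len_range[2], max(1, floor(slot * 0.8)))
        if (max_len < 1) abort("chromosome too short for the requested features.")
        lens <- floor(stats::runif(n, min(len_range[1], max_len), max_len + 1))
        offs <- floor(stats::runif(n, 0, slot - lens))
        start <- (seq_len(n) - 1) * slot + offs + 1
        tibble(chrom = ch, start = as.integer(start),
               end = as.integer(start + lens - 1),
               kind = sample(kinds, n, replace = TRUE, prob = kind_probs))
      })
      dplyr::bind_rows(out)
    })
  }
  genes <- place(params$n_genes, params$gene_length,
                 c("GENE", "PSEUDO", "RNA", "CDS", "UTR"),
                 c(0.6, 0.1, 0.1, 0.1, 0.1), "G", "genes")
  tfbs <- place(params$n_tfbs, params$tfbs_length, "TFBS", 1, "T", "tfbs")
  genes$id <- sprintf("G%04d", seq_len(nrow(genes)))
  tfbs$id <- sprintf("T%04d", seq_len(nrow(tfbs)))
  features <- dplyr::bind_rows(genes, tfbs)[
    c("id", "chrom", "start", "end", "kind")]
  list(genome = genome, features = features)
}

# alternating A/B compartment labels in geometric-length blocks
compartment_labels <- function(chrom_lengths, resolution, mean_blocks, seed) {
  purrr::imap(as.list(chrom_lengths), function(len, ch) {
    n <- ceiling(len / resolution)
    with_seed(substream_seed(seed, paste0("compartments_", ch)), {
      labels <- character(0)
      lab <- "A"
      while (length(labels) < n) {
        blk <- 1L + stats::rgeom(1, 1 / mean_blocks)
        labels <- c(labels, rep(lab, blk))
        lab <- if (lab == "A") "B" else "A"
      }
      labels[seq_len(n)]
    })
  })
}

# derivative-chromosome segment map for a tail-exchange translocation
derivative_segments <- function(genome, tr) {
  la <- genome$length[[chrom_rank(tr$chrom_a, genome)]]
  lb <- genome$length[[chrom_rank(tr$chrom_b, genome)]]
  if (tr$breakpoint_a <= 0 || tr$breakpoint_a >= la ||
      tr$breakpoint_b <= 0 || tr$breakpoint_b >= lb) {
    abort("translocation breakpoint outside its chromosome.")
  }
  dplyr::bind_rows(
    tibble(der = paste0("der_", tr$chrom_a),
           der_start = c(1, tr$breakpoint_a + 1),
           src = c(tr$chrom_a, tr$chrom_b),
           src_start = c(1, tr$breakpoint_b + 1),
           src_end = c(tr$breakpoint_a, lb)),
    tibble(der = paste0("der_", tr$chrom_b),
           der_start = c(1, tr$breakpoint_b + 1),
           src = c(tr$chrom_b, tr$chrom_a),
           src_start = c(1, tr$breakpoint_a + 1),
           src_end = c(tr$breakpoint_b, la))
  )
}

#' Simulate a mapped read-pair table
#'
#' Draws `n_pairs` read pairs on the (possibly rearranged) genome:
#'
#' * intra-chromosomal pairs with separation density proportional to
#'   `d^-alpha` (inverse-CDF sampling on a 1 Kb grid), modulated by the
#'   compartment plaid — same-compartment ends enriched by `1 + plaid`,
#'   cross-compartment depleted by `1 - plaid`;
#' * inter-chromosomal pairs uniform over chromosome pairs weighted by
#'   length products;
#' * an exact planted fraction of multi-mapped records (decoy candidate
#'   locations on one end) and of short-separation records (separation
#'   below `min_distance`).
#'
#' When `params$translocation` is set, pairs are drawn on the derivative
#' chromosomes (tail exchange at the breakpoints) and mapped back to
#' reference coordinates, which plants the dense inter-chromosomal corner
#' blocks that translocation detection looks for.
#'
#' @param genome Chromosome-length table (typically
#'   `simulate_genome(params)$genome`).
#' @param params A [sim_params()] object.
#' @return Long-form candidate tibble (the [read_pairs()] layout) with a
#'   `"truth"` attribute: a list with the planted artifact counts, the
#'   compartment-label table and the translocation spec.
#' @export
simulate_pairs <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  genome <- check_genome(genome)
  n <- params$n_pairs
  tr <- params$translocation
  samp_genome <- genome
  segs <- NULL
  if (!is.null(tr)) {
    segs <- derivative_segments(genome, tr)
    samp_genome <- dplyr::summarise(
      dplyr::group_by(segs, chrom = .data$der),
      length = sum(.data$src_end - .data$src_start + 1), .groups = "drop"
    )
    untouched <- genome[!genome$chrom %in% c(tr$chrom_a, tr$chrom_b), ]
    samp_genome <- dplyr::bind_rows(samp_genome, untouched)
  }
  labels <- compartment_labels(
    setNames(samp_genome$length, samp_genome$chrom),
    params$compartment_resolution, params$compartment_mean_blocks,
    params$seed
  )

  n_multi <- round(params$multi_map_frac * n)
  n_short <- round(params$short_pair_frac * n)
  category <- with_seed(substream_seed(params$seed, "categories"), {
    cat <- rep("normal", n)
    special <- sample.int(n, n_multi + n_short)
    cat[special[seq_len(n_multi)]] <- "multi"
    if (n_short > 0) cat[special[n_multi + seq_len(n_short)]] <- "short"
    cat
  })

  is_inter <- with_seed(substream_seed(params$seed, "inter"), {
    stats::runif(n) < params$inter_frac & category != "short"
  })

  pos <- matrix(NA_integer_, n, 2)
  chr <- matrix(NA_character_, n, 2)

  # --- intra pairs -----------------------------------------------------
  intra_idx <- which(!is_inter & category != "short")
  if (length(intra_idx)) {
    with_seed(substream_seed(params$seed, "intra"), {
      ch <- sample(samp_genome$chrom, length(intra_idx), replace = TRUE,
                   prob = samp_genome$length)
      p1 <- integer(length(intra_idx)); p2 <- integer(length(intra_idx))
      for (c_i in seq_len(nrow(samp_genome))) {
        chn <- samp_genome$chrom[c_i]
        len <- samp_genome$length[c_i]
        sel <- which(ch == chn)
        if (!length(sel)) next
        grid <- seq(params$min_distance, len - 1000, by = 1000)
        # per-locus-pair rate d^-alpha times the number of placements (len - d)
        # gives the marginal separation density of a uniform-rate process
        w <- grid^(-params$alpha) * (len - grid)
        lab <- labels[[chn]]
        pend <- sel
        while (length(pend)) {
          d <- grid[sample.int(length(grid), length(pend), replace = TRUE,
                               prob = w)] +
            floor(stats::runif(length(pend), 0, 1000))
          s <- 1 + floor(stats::runif(length(pend)) * (len - d))
          e <- s + d
          b1 <- lab[floor((s - 1) / params$compartment_resolution) + 1]
          b2 <- lab[floor((e - 1) / params$compartment_resolution) + 1]
          acc_p <- ifelse(b1 == b2, (1 + params$plaid) / 2,
                          (1 - params$plaid) / 2)
          keep <- stats::runif(length(pend)) < acc_p
          p1[pend[keep]] <- as.integer(s[keep])
          p2[pend[keep]] <- as.integer(e[keep])
          pend <- pend[!keep]
        }
      }
      pos[intra_idx, 1] <- p1
      pos[intra_idx, 2] <- p2
      chr[intra_idx, 1] <- ch
      chr[intra_idx, 2] <- ch
    })
  }

  # --- short-separation artifact pairs ---------------------------------
  short_idx <- which(category == "short")
  if (length(short_idx)) {
    with_seed(substream_seed(params$seed, "short"), {
      ch <- sample(samp_genome$chrom, length(short_idx), replace = TRUE,
                   prob = samp_genome$length)
      len <- samp_genome$length[match(ch, samp_genome$chrom)]
      d <- floor(stats::runif(length(short_idx), 50, params$min_distance))
      s <- 1 + floor(stats::runif(length(short_idx)) * (len - d))
      pos[short_idx, 1] <- as.integer(s)
      pos[short_idx, 2] <- as.integer(s + d)
      chr[short_idx, 1] <- ch
      chr[short_idx, 2] <- ch
    })
  }

  # --- inter pairs ------------------------------------------------------
  inter_idx <- which(is_inter)
  if (length(inter_idx)) {
    if (nrow(samp_genome) < 2) abort("inter pairs require >= 2 chromosomes.")
    with_seed(substream_seed(params$seed, "inter_pos"), {
      cp <- utils::combn(seq_len(nrow(samp_genome)), 2)
      wp <- samp_genome$length[cp[1, ]] * samp_genome$length[cp[2, ]]
      pick <- sample.int(ncol(cp), length(inter_idx), replace = TRUE, prob = wp)
      c1 <- cp[1, pick]; c2 <- cp[2, pick]
      pos[inter_idx, 1] <- as.integer(1 + floor(stats::runif(length(inter_idx)) *
                                                  samp_genome$length[c1]))
      pos[inter_idx, 2] <- as.integer(1 + floor(stats::runif(length(inter_idx)) *
                                                  samp_genome$length[c2]))
      chr[inter_idx, 1] <- samp_genome$chrom[c1]
      chr[inter_idx, 2] <- samp_genome$chrom[c2]
    })
  }

  # --- map derivative coordinates back to the reference genome ----------
  if (!is.null(segs)) {
    map_back <- function(chv, pv) {
      out_c <- chv; out_p <- pv
      for (k in seq_len(nrow(segs))) {
        seg_len <- segs$src_end[k] - segs$src_start[k] + 1
        sel <- chv == segs$der[k] & pv >= segs$der_start[k] &
          pv < segs$der_start[k] + seg_len
        out_c[sel] <- segs$src[k]
        out_p[sel] <- as.integer(segs$src_start[k] + (pv[sel] - segs$der_start[k]))
      }
      list(chrom = out_c, pos = out_p)
    }
    m1 <- map_back(chr[, 1], pos[, 1]); m2 <- map_back(chr[, 2], pos[, 2])
    chr[, 1] <- m1$chrom; pos[, 1] <- m1$pos
    chr[, 2] <- m2$chrom; pos[, 2] <- m2$pos
  }

  # --- assemble candidate table with decoys ------------------------------
  ids <- sprintf("r%07d", seq_len(n))
  strands <- with_seed(substream_seed(params$seed, "strands"), {
    matrix(sample(c("+", "-"), 2 * n, replace = TRUE), n, 2)
  })
  base <- tibble(
    read_id = rep(ids, 2),
    end = rep(c(1L, 2L), each = n),
    cand = 1L,
    chrom = c(chr[, 1], chr[, 2]),
    pos = c(pos[, 1], pos[, 2]),
    strand = c(strands[, 1], strands[, 2]),
    read_length = as.integer(params$read_length)
  )
  multi_idx <- which(category == "multi")
  if (length(multi_idx)) {
    decoys <- with_seed(substream_seed(params$seed, "decoys"), {
      which_end <- sample(c(1L, 2L), length(multi_idx), replace = TRUE)
      n_extra <- sample(1:2, length(multi_idx), replace = TRUE)
      rec <- rep(seq_along(multi_idx), n_extra)
      cand <- 1L + sequence(n_extra)
      ci <- sample.int(nrow(genome), length(rec), replace = TRUE)
      tibble(
        read_id = ids[multi_idx[rec]],
        end = which_end[rec],
        cand = cand,
        chrom = genome$chrom[ci],
        pos = as.integer(1 + floor(stats::runif(length(rec)) *
                                     genome$length[ci])),
        strand = sample(c("+", "-"), length(rec), replace = TRUE),
        read_length = as.integer(params$read_length)
      )
    })
    base <- dplyr::bind_rows(base, decoys)
  }
  out <- dplyr::arrange(base, match(.data$read_id, ids), .data$end, .data$cand)
  attr(out, "truth") <- list(
    planted = list(n_multi = n_multi, n_short = n_short),
    compartments = purrr::imap_dfr(labels, function(l, ch) {
      tibble(chrom = ch, bin = seq_along(l) - 1L, label = l)
    }),
    translocation = tr,
    sampling_genome = samp_genome
  )
  out
}

#' Simulate read pairs carrying a planted reciprocal translocation
#'
#' Thin wrapper over [simulate_pairs()] that requires
#' `params$translocation` to be set: pairs are drawn on the derivative
#' chromosomes (distance decay across the junctions) and mapped back to
#' reference coordinates, producing the dense inter-chromosomal corner
#' blocks of a reciprocal translocation.
#'
#' @inheritParams simulate_pairs
#' @return See [simulate_pairs()].
#' @export
plant_translocation <- function(genome, params) {
  if (is.null(params$translocation)) {
    abort("params$translocation must be set; see sim_params().")
  }
  simulate_pairs(genome, params)
}
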