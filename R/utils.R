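# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a component name,
# so each stochastic component draws from its own stream and adding a new
# component never shifts the draws of an existing one.
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((abs(seed) * 2654435761 + h * 40503) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Validate a chromosome-length table and return it with chrom as character,
# preserving the row order (which defines the canonical chromosome order).
check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must be a data frame with columns `chrom` and `length`.")
  }
  genome <- as_tibble(genome)
  genome$chrom <- as.character(genome$chrom)
  if (anyDuplicated(genome$chrom)) abort("duplicated chromosome names in `genome`.")
  if (any(genome$length <= 0)) abort("chromosome lengths must be positive.")
  genome
}

chrom_rank <- function(chrom, genome) {
  r <- match(chrom, genome$chrom)
  if (anyNA(r)) {
    abort(paste0(
      "unknown chromosome(s): ",
      paste(unique(chrom[is.na(r)]), collapse = ", ")
    ))
  }
  r
}
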