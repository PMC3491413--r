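# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps generators deterministic without
# leaking global state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream tag.
subSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# 0-based half-open [start0, end0) -> 1-based closed GRanges coordinates.
gr0 <- function(chrom, start0, end0, strand = "*", layout = NULL, ...) {
  gr <- if (length(chrom) == 0L) GRanges() else
    GRanges(seqnames = chrom,
            ranges = IRanges(start = start0 + 1, end = end0),
            strand = strand, ...)
  if (!is.null(layout)) gr <- applyLayout(gr, layout)
  gr
}

# Attach a genome layout (named lengths) to a GRanges; error on unknown
# chromosomes rather than dropping them silently.
applyLayout <- function(gr, layout) {
  layout <- checkLayout(layout)
  bad <- setdiff(unique(as.character(seqnames(gr))), names(layout))
  if (length(bad))
    stop("chromosome(s) not in genome layout: ", paste(bad, collapse = ", "))
  seqlevels(gr) <- names(layout)
  seqlengths(gr) <- layout
  gr
}

checkLayout <- function(layout) {
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    stop("genome layout must be a named vector of chromosome lengths")
  if (any(layout <= 0)) stop("all chromosome lengths must be positive")
  storage.mode(layout) <- "double"
  layout
}

# BED-style 0-based starts/ends of a GRanges.
start0 <- function(gr) start(gr) - 1L
end0 <- function(gr) end(gr)

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
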