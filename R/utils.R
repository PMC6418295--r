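# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# run `expr` under a fixed seed without clobbering the caller's RNG state;
# seed = NULL leaves the RNG stream alone (still reproducible if caller seeds)
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# random DNA of length n at a given GC fraction, as a character scalar
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# union length of a set of closed integer intervals
interval_union_width <- function(start, end) {
  if (length(start) == 0) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(IRanges::width(ir))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
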