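# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

logit <- function(p) log(p / (1 - p))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Reverse-complement for plain character vectors (ACGTN alphabet).
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# IUPAC ambiguity code -> concrete bases.
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Base set (sorted, concatenated) -> IUPAC code.
IUPAC_CODE <- local({
  codes <- names(IUPAC_BASES)
  keys <- vapply(IUPAC_BASES, function(b) paste(sort(b), collapse = ""), "")
  setNames(codes, keys)
})

iupac_to_regex <- function(word) {
  letters <- strsplit(word, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_BASES))
  if (length(bad) > 0) {
    abort(paste0("Invalid IUPAC letter(s) in motif word: ",
                 paste(unique(bad), collapse = ", ")))
  }
  paste(vapply(letters, function(l) {
    b <- IUPAC_BASES[[l]]
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
}

# Validate a DNA sequence over {A,C,G,T,N}; returns uppercase sequence.
check_dna <- function(seq, arg = "seq") {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort(paste0("`", arg, "` contains characters outside the ACGTN alphabet."))
  }
  seq
}

`%not_in%` <- function(x, table) !(x %in% table)

# Safe sampling without R's scalar-x gotcha (sample(5, 1) == sample(1:5, 1)).
resample <- function(x, k) x[sample.int(length(x), k)]
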