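# Internal helpers shared across modules.

# The 20 standard amino acids, in the conventional one-letter ordering used by
# substitution matrices (A R N D C Q E G H I L K M F P S T W Y V).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library code does not perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Character matrix (rows = sequences) from equal-length strings.
seq_matrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    stop("sequences are not aligned: lengths differ (", paste(unique(n), collapse = ", "), ")")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a packaged fixture file
#'
#' Convenience accessor for the plain-text fixtures shipped under
#' `inst/extdata` (the transcriptions of the published survey tables and the
#' family-to-group catalog).
#'
#' @param file File name within the package's `extdata` directory; with no
#'   argument, lists available fixtures.
#' @return A file path (or a character vector of file names).
#' @export
census_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "bhlhcensus")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged fixture named '", file, "'")
  path
}
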