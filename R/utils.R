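# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; case-insensitive, returns upper case.
#'
#' @param x a single DNA string over A/C/G/T (IUPAC ambiguity codes are
#'   complemented where defined, `N` maps to `N`).
#' @return the reverse complement, upper case.
#' @examples
#' revcomp("CTTTGC") # "GCAAAG"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTRYKMBVDHN", "TGCAYRMKVBHDN", toupper(x))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. Seeds are explicit arguments throughout the package, never global
# state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a global seed and a stage name.
# Keyed by the stage label so inserting a stage does not reshuffle the
# randomness of the others; result always fits a 32-bit signed integer.
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, nzchar(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) %% 2147480 * 1000 + h) %% 2147483647)
}

# polynomial rolling hash of a character scalar, hex string; used for
# config provenance in reports (stays within exact double arithmetic)
hash_string <- function(x) {
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 131 + k) %% 2147483647
  sprintf("%08x", h)
}

# Parse a quantity string such as "85 nM", "1.5e-7 M", "44.5 C" into a
# number in base units (molar for concentrations, degrees Celsius for
# temperatures). Bare numerics pass through unchanged.
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([a-zA-Z°]*)\\s*$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse quantity: ", x)
  val <- as.numeric(m[2])
  unit <- m[3]
  if (!nzchar(unit)) return(val)
  scale <- switch(unit,
    "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6, "nM" = 1e-9,
    "pM" = 1e-12, "C" = 1, "°C" = 1, "s" = 1, "RU" = 1, "bp" = 1,
    "nm" = 1,
    stop("unknown unit in quantity: ", x)
  )
  val * scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a
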