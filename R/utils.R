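`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome labels to UCSC "chr*" form
#'
#' Accepts labels such as `"x"`, `"X"`, `"chrX"`, `"19"`, `"chr19"`, `"MT"`
#' and returns the canonical `"chr*"` spelling (`"chrX"`, `"chr19"`,
#' `"chrM"`). Mitochondrial `"MT"` collapses to `"chrM"`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chromosome <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  x[x == "MT"] <- "M"
  paste0("chr", x)
}

#' Chromosome universe for an assembly
#'
#' @param assembly `"mouse"` (chr1-19 + chrX) or `"human"` (chr1-22 + chrX).
#'   chrY and chrM are never part of the X:A universe.
#' @param autosomes_only drop chrX from the returned set.
#' @return character vector of chromosome labels.
#' @export
chromosome_set <- function(assembly = c("mouse", "human"),
                           autosomes_only = FALSE) {
  assembly <- match.arg(assembly)
  n <- if (assembly == "mouse") 19L else 22L
  out <- paste0("chr", seq_len(n))
  if (!autosomes_only) out <- c(out, "chrX")
  out
}

#' Evaluate code under a fixed seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Stable integer hash of (master seed, stage label) so that adding a stage
#' to a pipeline never perturbs the draws of the others. Result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(label) == 1L, is.character(label))
  bytes <- utf8ToInt(label)
  h <- sum(bytes * seq_along(bytes)) %% 2147483647
  v <- ((as.numeric(master) %% 2147483647) * 48271) %% 2147483647
  as.integer((v + h * 1009) %% 2147483646) + 1L
}

# Fixed 6-significant-digit formatting so written tables are byte-stable.
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

# log2 with the toolchain collapse convention: linear values in (0, 1) map
# to log2 value 0; zeros stay "not expressed" (NA).
log2_collapsed <- function(v) {
  out <- rep(NA_real_, length(v))
  pos <- !is.na(v) & v > 0
  out[pos] <- pmax(log2(v[pos]), 0)
  out
}
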