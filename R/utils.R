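# Internal helpers: variant keys, deterministic sub-seeding, local RNG scope.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F", Gly = "G",
  His = "H", Ile = "I", Lys = "K", Leu = "L", Met = "M", Asn = "N",
  Pro = "P", Gln = "Q", Arg = "R", Ser = "S", Thr = "T", Val = "V",
  Trp = "W", Tyr = "Y"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

variant_id <- function(protein, position, ref, alt) {
  paste(protein, position, ref, alt, sep = ":")
}

key_df_ids <- function(df) {
  variant_id(df$protein, df$position, df$ref, df$alt)
}

#' Derive a deterministic sub-seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed through named
#' substreams (one per artifact), so regenerating one component leaves the
#' others unchanged. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Character/numeric labels naming the substream.
#' @return A single integer in `[0, 2^31 - 20)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
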