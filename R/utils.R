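#' @keywords internal
"_PACKAGE"

# shared argument checks -------------------------------------------------

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

check_seed <- function(seed) {
  stop_if_not(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite integer")
  as.integer(seed)
}

#' Min-max rescale a numeric vector to [0, 1]
#'
#' Constant vectors map to 0.5 everywhere, the convention used throughout the
#' package for per-feature rescaling of oscillation profiles and for
#' interactor expression profiles.
#'
#' @param x numeric vector (NAs tolerated and preserved).
#' @return numeric vector in \[0, 1\].
#' @export
minmax_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("minmax_scale: no finite values", call. = FALSE)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    out[is.na(x)] <- NA_real_
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}
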