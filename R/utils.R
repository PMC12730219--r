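#' Round half away from zero
#'
#' Deterministic rounding used throughout the preprocessing and augmentation
#' operators: ties at .5 always round up (for the nonnegative intensity
#' ranges handled here), unlike [base::round()] which rounds half to even.
#'
#' @param x numeric vector or array.
#' @return `x` rounded to the nearest integer, ties upward.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Build a subject-slice identifier
#'
#' Identifiers take the form `"sub_XX_slice_YY"`. The slice index is printed
#' verbatim, zero-padded to a minimum width of 2 (so index 5 becomes `05`
#' but 115 stays `115`).
#'
#' @param subject_id subject token such as `"sub_05"`.
#' @param slice_index 0-based integer slice index.
#' @return identifier string.
#' @seealso [parse_identifier()] for the exact inverse.
#' @examples
#' make_identifier("sub_05", 115)
#' @export
make_identifier <- function(subject_id, slice_index) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  slice_index <- as.integer(slice_index)
  if (is.na(slice_index) || slice_index < 0L)
    stop("slice_index must be a nonnegative integer")
  sprintf("%s_slice_%02d", subject_id, slice_index)
}

#' Parse a subject-slice identifier
#'
#' Exact inverse of [make_identifier()]: `"sub_05_slice_115"` parses back to
#' `("sub_05", 115)`. Malformed tokens raise an error.
#'
#' @param token identifier string.
#' @return list with elements `subject_id` (string) and `slice_index`
#'   (integer).
#' @examples
#' parse_identifier("sub_05_slice_115")
#' @export
parse_identifier <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  m <- regmatches(token, regexec("^(sub_[0-9]+)_slice_([0-9]+)$", token))[[1]]
  if (length(m) != 3L)
    stop("malformed identifier: ", sQuote(token),
         " (expected \"sub_XX_slice_YY\")")
  list(subject_id = m[2], slice_index = as.integer(m[3]))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# clip to [0, 255] then round half-up: the final step of every photometric
# operator so outputs are valid 8-bit images.
clip_round_255 <- function(x) round_half_up(pmin(pmax(x, 0), 255))

is_binary <- function(x) all(x %in% c(0, 1))
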