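#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup
#' @importFrom purrr map map_dbl map_int map2 pmap imap
#' @keywords internal
"_PACKAGE"

# population standard deviation (divide by N): the convention GFP uses
pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

assert_that <- function(ok, msg, class = "msrqa_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# fan a root seed out to per-stage seeds without exceeding .Machine$integer.max
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

spk_levels <- c("SPK1", "SPK2", "NONE")

as_label_factor <- function(x) factor(as.character(x), levels = spk_levels)
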