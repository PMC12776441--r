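# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-position profile test
#'
#' @param x A `uvf_profile_test`.
#' @param ... Unused.
#' @return A plain tibble of the per-cell results.
#' @method tidy uvf_profile_test
#' @export
tidy.uvf_profile_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.uvf_profile_test
#' @method glance uvf_profile_test
#' @export
glance.uvf_profile_test <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 n_enriched = sum(x$significant &
                                    x$direction == "enriched",
                                  na.rm = TRUE),
                 n_depleted = sum(x$significant &
                                    x$direction == "depleted",
                                  na.rm = TRUE),
                 min_q = suppressWarnings(min(x$q, na.rm = TRUE)),
                 max_abs_z = suppressWarnings(max(abs(x$z),
                                                  na.rm = TRUE)),
                 threshold = attr(x, "threshold"),
                 test = attr(x, "test"))
}

#' Tidy a repair bootstrap test
#'
#' @param x A `uvf_repair_test`.
#' @param ... Unused.
#' @method tidy uvf_repair_test
#' @export
tidy.uvf_repair_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$composition <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.uvf_repair_test
#' @method glance uvf_repair_test
#' @export
glance.uvf_repair_test <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 max_z = suppressWarnings(max(x$z, na.rm = TRUE)),
                 n_boot = attr(x, "n_boot"),
                 kernel = attr(x, "kernel"),
                 threshold = attr(x, "threshold"))
}

#' Tidy a projected-vs-actual concordance fit
#'
#' @param x A `uvf_concordance`.
#' @param ... Unused.
#' @return Per-position tibble with residual z and discordance flags.
#' @method tidy uvf_concordance
#' @export
tidy.uvf_concordance <- function(x, ...) {
  x$positions
}

#' @rdname tidy.uvf_concordance
#' @method glance uvf_concordance
#' @export
glance.uvf_concordance <- function(x, ...) {
  tibble::tibble(r = x$r, slope = x$slope, intercept = x$intercept,
                 n_positions = nrow(x$positions),
                 n_discordant = x$n_discordant,
                 baseline_mean_r = x$baseline_mean)
}
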