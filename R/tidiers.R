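#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for capmeth result objects
#'
#' `tidy()` returns the per-unit table of a result (per-contig coverage,
#' per-site tests, per-probe selections); `glance()` returns a one-row
#' summary.
#'
#' @param x A capmeth result object.
#' @param ... Unused.
#' @return A tibble.
#' @name capmeth-tidiers
NULL

#' @rdname capmeth-tidiers
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) x$per_contig

#' @rdname capmeth-tidiers
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) x$aggregate

#' @rdname capmeth-tidiers
#' @method tidy capmeth_dm
#' @export
tidy.capmeth_dm <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname capmeth-tidiers
#' @method glance capmeth_dm
#' @export
glance.capmeth_dm <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    n_tested = attr(x, "n_tested"),
    n_significant = attr(x, "n_significant"),
    frac_significant = attr(x, "frac_significant"),
    min_depth = p$min_depth,
    alpha = p$alpha,
    min_diff = p$min_diff
  )
}

#' @rdname capmeth-tidiers
#' @method glance conversion_efficiency
#' @export
glance.conversion_efficiency <- function(x, ...) {
  tibble::tibble(
    efficiency_pct = x$efficiency_pct,
    n_observations = x$n_observations,
    n_converted = x$n_converted,
    n_unconverted = x$n_unconverted,
    mean_depth = x$mean_depth,
    pct_covered = x$pct_covered,
    base_space_mapped = x$base_space_mapped,
    defined = x$defined
  )
}

#' @rdname capmeth-tidiers
#' @method glance correction_report
#' @export
glance.correction_report <- function(x, ...) {
  tibble::tibble(
    n_snps_total = x$n_snps_total,
    n_ct_ga = x$n_ct_ga,
    n_at_cg = x$n_at_cg,
    n_analyzable_cytosines = x$n_analyzable_cytosines,
    pct_calls_eliminated = x$pct_calls_eliminated,
    n_cytosines_added = x$n_cytosines_added,
    pct_cytosines_added = x$pct_cytosines_added
  )
}

#' @rdname capmeth-tidiers
#' @method tidy probe_set
#' @export
tidy.probe_set <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$selected, copy = "selected"),
    dplyr::mutate(x$boosted, copy = "boosted")
  )
}

#' @rdname capmeth-tidiers
#' @method glance probe_set
#' @export
glance.probe_set <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$selected),
    n_forced = sum(x$selected$forced),
    n_boosted = nrow(x$boosted),
    target_count = x$target_count,
    mean_gc = mean(x$selected$gc_content %||% gc_fraction(x$selected$seq),
      na.rm = TRUE
    )
  )
}
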