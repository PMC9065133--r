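#' Tidy a step-count fit
#'
#' Returns the qualifying-peak table of the pairwise-difference density:
#' one row per positive-side local maximum with its position (arb.
#' units), height, height relative to the tallest positive peak, and
#' whether it qualified.
#'
#' @param x A `step_fit` from [estimate_step_count()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy step_fit
#' @export
tidy.step_fit <- function(x, ...) {
  as_tibble(x$pdd$peaks)
}

#' @rdname tidy.step_fit
#' @method glance step_fit
#' @export
glance.step_fit <- function(x, ...) {
  tibble(
    k_steps = x$k_steps,
    step_size_estimate = x$step_size_estimate,
    sigma_hat = x$sigma_hat,
    n_frames = x$n_frames,
    n_pairs = x$pdd$n_values,
    bandwidth = x$pdd$bandwidth,
    d_min = x$pdd$d_min,
    n_peaks = nrow(x$pdd$peaks),
    n_qualifying = sum(x$pdd$peaks$qualifying)
  )
}

#' @rdname tidy.step_fit
#' @method tidy pdd_density
#' @export
tidy.pdd_density <- function(x, ...) {
  as_tibble(x$peaks)
}

#' Tidy a pipeline run
#'
#' @param x A `bleach_run` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()` returns the per-spot counts tibble; `glance()` one
#'   row per condition of summary statistics.
#' @method tidy bleach_run
#' @export
tidy.bleach_run <- function(x, ...) {
  as_tibble(x$counts)
}

#' @rdname tidy.bleach_run
#' @method glance bleach_run
#' @export
glance.bleach_run <- function(x, ...) {
  if (is.null(x$summary)) return(tibble())
  as_tibble(x$summary)
}
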