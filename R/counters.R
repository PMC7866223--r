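## Operation counters: the collapsed nodal-adjoint construction is an
## operation-count claim as much as a numerical one (ns forward solves per
## sweep, one length-np vector product per Jacobian row, no hidden solves),
## so the solver and Jacobian assembly are instrumented.

.mwt_counters <- new.env(parent = emptyenv())

#' Reset the package operation counters
#'
#' @return invisibly, the zeroed counter list.
#' @seealso [mwt_counters()]
#' @export
reset_counters <- function() {
  .mwt_counters$forward_solves <- 0L
  .mwt_counters$jacobian_rows <- 0L
  invisible(mwt_counters())
}

#' Read the package operation counters
#'
#' `forward_solves` counts single-transmitter forward solutions;
#' `jacobian_rows` counts Jacobian rows assembled as vector-vector products.
#'
#' @return named list of counters.
#' @export
mwt_counters <- function() {
  if (is.null(.mwt_counters$forward_solves)) reset_counters()
  list(forward_solves = .mwt_counters$forward_solves,
       jacobian_rows = .mwt_counters$jacobian_rows)
}

.count <- function(what, by = 1L) {
  if (is.null(.mwt_counters[[what]])) reset_counters()
  .mwt_counters[[what]] <- .mwt_counters[[what]] + as.integer(by)
  invisible(NULL)
}
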