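#' Build an index system from a column of q-statistics
#'
#' Selects the covariates that form a vegetation pair's index system: keep
#' variables with q strictly greater than `threshold`, sort by q descending
#' (ties broken by ascending variable name), and truncate to the top `k`.
#' If fewer than `k` variables pass, all passers are returned and the result
#' is flagged `short = TRUE` with a warning; the list is never padded with
#' sub-threshold variables.
#'
#' @param qcolumn Named numeric vector of q values (one per candidate
#'   variable), or a `qtable` data frame from [q_table()].
#' @param threshold Strict lower bound on q (default 0.3).
#' @param k Maximum number of variables retained (default 4).
#' @param pair Optional [pair_spec()] recorded on the result.
#' @return An object of class `index_system`: list with `variables` (ordered
#'   names), `q` (their q values), `threshold`, `k`, `short`, `pair`.
#' @examples
#' select_index_system(c(a = 0.5, b = 0.2, c = 0.45, d = 0.31, e = 0.44,
#'                       f = 0.35))
#' @export
select_index_system <- function(qcolumn, threshold = 0.3, k = 4, pair = NULL) {
  if (inherits(qcolumn, "qtable") || is.data.frame(qcolumn)) {
    if (is.null(pair)) pair <- attr(qcolumn, "pair")
    qcolumn <- stats::setNames(qcolumn$q, qcolumn$variable)
  }
  if (length(qcolumn) < 1L) stop("'qcolumn' must be nonempty")
  if (is.null(names(qcolumn)) || any(names(qcolumn) == ""))
    stop("'qcolumn' must be named")
  if (threshold < 0 || threshold >= 1) stop("'threshold' must be in [0, 1)")
  if (k < 1) stop("'k' must be >= 1")
  pass <- qcolumn[qcolumn > threshold]
  if (length(pass) == 0L)
    stop("empty index system: no variable has q > ", threshold)
  o <- order(-pass, names(pass))
  pass <- pass[o]
  short <- length(pass) < k
  if (short)
    warning(sprintf("only %d variable(s) exceed q = %g (requested top %d)",
                    length(pass), threshold, k))
  sel <- utils::head(pass, k)
  structure(list(variables = names(sel), q = unname(sel),
                 threshold = threshold, k = as.integer(k),
                 short = short, pair = pair),
            class = "index_system")
}

#' @export
print.index_system <- function(x, ...) {
  hdr <- if (!is.null(x$pair)) sprintf(" (pair %s)", x$pair$group_id) else ""
  cat(sprintf("<index_system>%s q > %g, top %d%s\n", hdr, x$threshold, x$k,
              if (x$short) " [short]" else ""))
  for (i in seq_along(x$variables))
    cat(sprintf("  %-14s q = %.6f\n", x$variables[i], x$q[i]))
  invisible(x)
}

#' @export
format.index_system <- function(x, ...)
  paste(x$variables, collapse = ", ")
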