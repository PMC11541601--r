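# Iterative purified-anchor DIF detection and formal likelihood-ratio
# testing with Benjamini-Hochberg adjustment.

#' Purify an anchor set for DIF testing
#'
#' Stage-one sweep: for each item in turn, compare the fully anchored
#' two-group model against the model freeing that item's (a, b), all other
#' items held as the temporary DIF-free anchor set, by a likelihood-ratio
#' test with 2 degrees of freedom. Items significant at `alpha`
#' (unadjusted; purification is deliberately liberal) become DIF
#' candidates; the remaining items form the purified anchor set. If every
#' item flags — or fewer than `minAnchors` survive — items are ranked by
#' the BIC improvement gained by freeing them and the `minAnchors` items
#' with the smallest improvement (ties broken by item order) are taken as
#' anchors.
#'
#' The focal latent mean and variance are re-estimated in every model of
#' the sweep, so true latent-mean differences (impact) are not mistaken
#' for DIF.
#'
#' @param data a [ResponseMatrix-class] with a two-level group factor.
#' @param alpha sweep significance level (default 0.05, unadjusted).
#' @param minAnchors smallest acceptable anchor set (default 3).
#' @param grid,control passed to [fitMultigroup()].
#' @return List with `anchors` (character), `sweep` (data.frame: item, lr,
#'   df, p, flagged, bicDiff), and `baseline` (the all-anchored
#'   [GroupModel-class], reusable as a warm start).
#' @export
purifyAnchors <- function(data, alpha = 0.05, minAnchors = 3L,
                          grid = quadratureGrid(), control = list()) {
  items <- itemNames(data)
  if (length(items) < 4L) stop("at least 4 items are required for purification")
  ctl <- .emControl(control)
  prep <- .prepareGroups(data, ctl)
  base <- .emMultigroup(prep, .buildConstraint(items, items), TRUE, grid, ctl)
  ll0 <- base@fit@logLik
  bic0 <- BIC(base@fit)
  warm <- .warmStart(base)
  lr <- bicDiff <- numeric(length(items))
  for (k in seq_along(items)) {
    fitK <- .emMultigroup(prep, .buildConstraint(items, setdiff(items, items[k])),
                          TRUE, grid, ctl, start = warm)
    lr[k] <- max(2 * (fitK@fit@logLik - ll0), 0)
    bicDiff[k] <- bic0 - BIC(fitK@fit)   # improvement from freeing item k
  }
  p <- stats::pchisq(lr, df = 2L, lower.tail = FALSE)
  flagged <- p < alpha
  sweep <- data.frame(item = items, lr = lr, df = 2L, p = p,
                      flagged = flagged, bicDiff = bicDiff)
  anchors <- items[!flagged]
  if (length(anchors) < minAnchors) {
    # stable rank on BIC improvement; smallest improvement = most DIF-free
    ord <- order(bicDiff)       # ties broken by item order (stable)
    anchors <- items[sort(ord[seq_len(minAnchors)])]
  }
  list(anchors = anchors, sweep = sweep, baseline = base)
}

#' Formal DIF tests against a purified anchor set
#'
#' Fits the single multigroup model in which the anchor items are
#' constrained equal across groups, all other items are free, and the
#' focal latent moments are estimated. Each non-anchor item is then tested
#' for joint (a, b) equality by a likelihood-ratio test (df = 2) against
#' the model that additionally constrains that item, with
#' Benjamini-Hochberg adjustment across the tested items.
#'
#' @param data a [ResponseMatrix-class] with a two-level group factor.
#' @param anchors the purified anchor set (non-empty, disjoint from the
#'   tested items).
#' @param alpha flagging level applied to BH-adjusted p-values.
#' @param grid,control passed to [fitMultigroup()].
#' @param sweep optional purification log stored with the result.
#' @return A [DIFTestResult-class]. The fitted full (DIF) model is
#'   attached as attribute `"model"`.
#' @export
testDif <- function(data, anchors, alpha = 0.05, grid = quadratureGrid(),
                    control = list(), sweep = NULL) {
  items <- itemNames(data)
  if (!length(anchors)) stop("anchor set must be non-empty")
  if (!all(anchors %in% items))
    stop("validation error: unknown anchor item(s): ",
         paste(setdiff(anchors, items), collapse = ", "))
  tested <- setdiff(items, anchors)
  ctl <- .emControl(control)
  prep <- .prepareGroups(data, ctl)
  full <- .emMultigroup(prep, .buildConstraint(items, anchors), TRUE, grid, ctl)
  warm <- .warmStart(full)
  lr <- numeric(length(tested))
  for (k in seq_along(tested)) {
    fitK <- .emMultigroup(prep, .buildConstraint(items, c(anchors, tested[k])),
                          TRUE, grid, ctl, start = warm)
    lr[k] <- max(2 * (full@fit@logLik - fitK@fit@logLik), 0)
  }
  p <- stats::pchisq(lr, df = 2L, lower.tail = FALSE)
  pbh <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(item = tested, lr = lr, df = rep(2L, length(tested)),
                    p = p, p_bh = pbh, flag = pbh < alpha)
  if (is.null(sweep))
    sweep <- data.frame(item = character(), lr = numeric(), df = integer(),
                        p = numeric(), flagged = logical(),
                        bicDiff = numeric())
  out <- new("DIFTestResult", table = tab, anchors = anchors,
             alpha = alpha, sweep = sweep)
  attr(out, "model") <- full
  out
}

#' One-parameter follow-up DIF tests
#'
#' For an item already flagged by the joint test, tests slope-only and
#' location-only equality separately (df = 1 each) by constraining the one
#' parameter across groups while the other stays free. Reported for
#' interpretation; flagging is based on the joint test.
#'
#' @param data a [ResponseMatrix-class] with a two-level group factor.
#' @param anchors the anchor set used in the formal test.
#' @param item the non-anchor item to decompose.
#' @param grid,control passed to [fitMultigroup()].
#' @return data.frame with rows "a" and "b": lr, df, p.
#' @export
difFollowUp <- function(data, anchors, item, grid = quadratureGrid(),
                        control = list()) {
  items <- itemNames(data)
  if (!item %in% setdiff(items, anchors))
    stop("'item' must be a non-anchor item")
  ctl <- .emControl(control)
  prep <- .prepareGroups(data, ctl)
  full <- .emMultigroup(prep, .buildConstraint(items, anchors), TRUE, grid, ctl)
  warm <- .warmStart(full)
  lr <- vapply(c("a", "b"), function(parm) {
    fitP <- .emMultigroup(
      prep, .buildConstraint(items, anchors, stats::setNames(parm, item)),
      TRUE, grid, ctl, start = warm)
    max(2 * (full@fit@logLik - fitP@fit@logLik), 0)
  }, numeric(1L))
  data.frame(parameter = c("a", "b"), lr = unname(lr), df = 1L,
             p = stats::pchisq(unname(lr), df = 1L, lower.tail = FALSE))
}
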