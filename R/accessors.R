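# Accessors, constructors and show methods for the core containers.

#' Construct a ResponseMatrix
#'
#' @param responses matrix or data.frame of 0/1/NA outcomes, one column per
#'   item; column names are the item identifiers.
#' @param group optional factor (or vector coerced to factor) of group
#'   labels, one per respondent; the first level is the reference group.
#' @return A [ResponseMatrix-class].
#' @examples
#' rm <- responseMatrix(cbind(SC21 = c(1, 0, 1), SC22 = c(0, 0, 1)),
#'                      group = c("f", "m", "f"))
#' itemNames(rm)
#' @export
responseMatrix <- function(responses, group = NULL) {
  m <- as.matrix(responses)
  storage.mode(m) <- "integer"
  if (is.null(group)) group <- factor(character())
  else {
    if (!is.factor(group)) group <- factor(group)
    group <- droplevels(group)
  }
  new("ResponseMatrix", responses = m, group = group)
}

#' @rdname ResponseMatrix-class
#' @export
setMethod("responses", "ResponseMatrix", function(object) object@responses)

#' @rdname ResponseMatrix-class
#' @export
setMethod("groupLabels", "ResponseMatrix", function(object) object@group)

#' @rdname ResponseMatrix-class
#' @export
setMethod("itemNames", "ResponseMatrix", function(object) colnames(object@responses))

#' @rdname ResponseMatrix-class
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@responses))

setMethod("show", "ResponseMatrix", function(object) {
  d <- dim(object@responses)
  cat("ResponseMatrix:", d[1L], "respondents x", d[2L], "items\n")
  cat(" items:", paste(colnames(object@responses), collapse = ", "), "\n")
  if (length(object@group)) {
    tab <- table(object@group)
    cat(" groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                          collapse = ", "), "\n")
  } else cat(" groups: none (single group)\n")
  nmiss <- sum(is.na(object@responses))
  if (nmiss) cat(" missing responses:", nmiss, "\n")
})

#' Construct an ItemParameters set
#'
#' @param items character vector of item identifiers.
#' @param a discriminations (logistic slopes), > 0.
#' @param b difficulties on the latent-trait metric.
#' @param D logistic-to-normal-ogive scaling constant; 1.702 by default.
#' @return An [ItemParameters-class].
#' @examples
#' p <- itemParameters(c("SC21", "SC22"), a = c(3.518, 4.641), b = c(0.248, 0.206))
#' itemLoadings(p)
#' @export
itemParameters <- function(items, a, b, D = 1.702) {
  new("ItemParameters", items = as.character(items), a = as.numeric(a),
      b = as.numeric(b), D = as.numeric(D))
}

#' @rdname ItemParameters-class
#' @export
setMethod("itemNames", "ItemParameters", function(object) object@items)

#' @rdname ItemParameters-class
#' @export
setMethod("discrimination", "ItemParameters",
          function(object) stats::setNames(object@a, object@items))

#' @rdname ItemParameters-class
#' @export
setMethod("difficulty", "ItemParameters",
          function(object) stats::setNames(object@b, object@items))

#' @rdname ItemParameters-class
#' @export
setMethod("scalingConstant", "ItemParameters", function(object) object@D)

#' @rdname ItemParameters-class
#' @export
setMethod("itemLoadings", "ItemParameters", function(object)
  stats::setNames(loadingFromDiscrimination(object@a, object@D), object@items))

#' @rdname ItemParameters-class
#' @export
setMethod("itemCommunalities", "ItemParameters", function(object)
  itemLoadings(object)^2)

#' @rdname ItemParameters-class
#' @export
setMethod("length", "ItemParameters", function(x) length(x@items))

#' @rdname ItemParameters-class
#' @param i items to keep (index or name).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ItemParameters", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@items)
  itemParameters(x@items[i], x@a[i], x@b[i], x@D)
})

#' @rdname ItemParameters-class
#' @export
setMethod("as.data.frame", "ItemParameters", function(x, ...) {
  data.frame(item = x@items, a = x@a, b = x@b,
             lambda = unname(itemLoadings(x)), h2 = unname(itemCommunalities(x)),
             row.names = NULL)
})

setMethod("show", "ItemParameters", function(object) {
  cat("ItemParameters (2PL, D =", format(object@D), ")\n")
  print(format(as.data.frame(object), digits = 4), row.names = FALSE)
})

#' @rdname FitSummary-class
#' @param object a FitSummary (or an object containing one).
#' @export
setMethod("fitSummary", "FitSummary", function(object) object)

#' @rdname TwoPLFit-class
#' @param object a TwoPLFit.
#' @export
setMethod("itemParams", "TwoPLFit", function(object) object@params)

#' @rdname TwoPLFit-class
#' @export
setMethod("fitSummary", "TwoPLFit", function(object) object@fit)

#' @rdname FitSummary-class
#' @param object a FitSummary.
#' @export
setMethod("logLik", "FitSummary", function(object)
  structure(object@logLik, df = object@nParameters, nobs = object@n,
            class = "logLik"))

#' @rdname FitSummary-class
#' @param ... ignored.
#' @param k ignored (fixed at 2, the classical AIC penalty).
#' @export
setMethod("AIC", "FitSummary", function(object, ..., k = 2)
  -2 * object@logLik + 2 * object@nParameters)

#' @rdname FitSummary-class
#' @export
setMethod("BIC", "FitSummary", function(object, ...)
  -2 * object@logLik + object@nParameters * log(object@n))

setMethod("show", "FitSummary", function(object) {
  cat(sprintf("logLik %.4f on %d parameters (n = %d)\n",
              object@logLik, object@nParameters, object@n))
  cat(sprintf("AIC %.2f  BIC %.2f  %s after %d EM cycles\n",
              AIC(object), BIC(object),
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
})

setMethod("show", "TwoPLFit", function(object) {
  cat("Two-parameter logistic IRT fit\n")
  show(object@params)
  show(object@fit)
})

#' @rdname LatentScore-class
#' @param x a LatentScore.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "LatentScore", function(x, ...)
  data.frame(eap = x@eap, psd = x@psd))

setMethod("show", "LatentScore", function(object) {
  cat("LatentScore:", length(object@eap), "respondents; EAP range",
      sprintf("[%.3f, %.3f]\n", min(object@eap), max(object@eap)))
})

setMethod("show", "GroupModel", function(object) {
  cat(sprintf("Multigroup 2PL: %s (reference) vs %s (focal)\n",
              object@groups[1L], object@groups[2L]))
  cat(" anchored items:",
      if (any(object@anchored)) paste(names(which(object@anchored)), collapse = ", ")
      else "none", "\n")
  cat(sprintf(" focal latent mean %.4f, variance %.4f (%s)\n",
              object@focalMean, object@focalVar,
              if (object@momentsEstimated) "estimated" else "fixed"))
  show(object@fit)
})

#' @rdname GroupModel-class
#' @param object a GroupModel.
#' @export
setMethod("fitSummary", "GroupModel", function(object) object@fit)

#' @rdname GroupModel-class
#' @export
setMethod("anchorItems", "GroupModel",
          function(object) names(which(object@anchored)))

#' @rdname DIFTestResult-class
#' @param object a DIFTestResult.
#' @export
setMethod("difTable", "DIFTestResult", function(object) object@table)

#' @rdname DIFTestResult-class
#' @export
setMethod("anchorItems", "DIFTestResult", function(object) object@anchors)

setMethod("show", "DIFTestResult", function(object) {
  cat("Formal DIF tests (joint a, b likelihood-ratio, BH-adjusted)\n")
  cat(" anchors:", paste(object@anchors, collapse = ", "), "\n")
  if (nrow(object@table))
    print(format(object@table, digits = 4), row.names = FALSE)
  else cat(" no non-anchor items to test\n")
  cat(sprintf(" flagged at adjusted p < %.3g: %s\n", object@alpha,
              if (any(object@table$flag)) paste(object@table$item[object@table$flag],
                                                collapse = ", ") else "none"))
})

setMethod("show", "TetrachoricMatrix", function(object) {
  cat("TetrachoricMatrix:", nrow(object@rho), "items\n")
  print(round(object@rho, 3))
  if (any(object@flags[upper.tri(object@flags)]))
    cat(" flagged pairs:", sum(object@flags[upper.tri(object@flags)]), "\n")
})

setMethod("show", "CFAFit", function(object) {
  cat("One-factor CFA (least squares on tetrachoric correlations)\n")
  print(round(data.frame(loading = object@loadings, h2 = object@h2,
                         item_rmsea = object@itemRmsea), 3))
  cat(sprintf("RMSEA %.3f  SRMSR %.3f  CFI %.3f  TLI %.3f  (n = %d)\n",
              object@rmsea, object@srmsr, object@cfi, object@tli, object@n))
})

setMethod("show", "ScreeningCutpoint", function(object) {
  cat(sprintf(
    "Screening cut: sum score >= %g (%s convention, t = %g) -> theta* = %.6f\n",
    object@cut, object@convention, object@t, object@thetaStar))
})

#' @rdname ClassificationIndices-class
#' @param object a ClassificationIndices.
#' @export
setMethod("indicesTable", "ClassificationIndices", function(object) object@table)

setMethod("show", "ClassificationIndices", function(object) {
  cat(sprintf("Classification indices (%s mode, %s variant)\n",
              object@mode, object@variant))
  print(format(object@table, digits = 4), row.names = FALSE)
  show(object@cut)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n =", object@n, "\n")
  if (length(object@groups) == 2L)
    cat(sprintf(" groups %s/%s (%.2f/%.2f), focal latent N(%.3f, %.3f)\n",
                object@groups[1L], object@groups[2L],
                object@proportions[1L], object@proportions[2L],
                object@focalMean, object@focalVar))
  else cat(" single group", object@groups, "\n")
  if (nrow(object@dif)) {
    cat(" injected DIF offsets:\n")
    print(object@dif, row.names = FALSE)
  } else cat(" no injected DIF\n")
  cat(" seed:", object@seed, "\n")
})

setMethod("show", "ScreeningRuleSet", function(object) {
  cat("ScreeningRuleSet:", length(object@rules), "rules over",
      length(object@questions), "gate questions\n")
  for (nm in names(object@rules))
    cat(sprintf("  %s: %s\n", nm, deparse1(object@rules[[nm]])))
})
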