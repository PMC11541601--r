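# The CIDI 3.0 internalising screening section: gate-question identifiers
# and the nine dichotomous screening rules that route respondents into the
# mood and anxiety diagnostic modules.

#' Gate-question identifiers
#'
#' The question identifiers of the internalising screening section, in
#' interview order. Compound rules (panic, irritability, worry, social
#' anxiety, agoraphobia) draw on several questions each.
#'
#' @return Character vector of 20 identifiers.
#' @export
gateQuestionNames <- function() c(
  "SC20", "SC20a", "SC21", "SC22", "SC23", "SC24", "SC25", "SC25a",
  "SC26", "SC26a", "SC26b",
  "SC29", "SC29a", "SC29.1", "SC29.2", "SC29.3",
  "SC30", "SC30.1", "SC30.2", "SC30.3")

#' The nine screening rules
#'
#' Boolean screen-in expressions over the yes-indicators of the gate
#' questions. Any answer other than "Yes" ("No", "Don't know", "Refused")
#' is negative, and screen-out is the logical complement of screen-in.
#' The rules, by targeted module: SC20 panic (either panic question),
#' SC21 depressed mood, SC22 discouragement, SC23 anhedonia, SC24
#' excitement/energy, SC25 irritability (both probes), SC26 worry/anxiety
#' (any of three probes), SC29 social anxiety and SC30 agoraphobia
#' (fear question(s) plus distress-or-avoidance plus excessiveness).
#'
#' @return A [ScreeningRuleSet-class].
#' @examples
#' screeningRules()
#' @export
screeningRules <- function() {
  new("ScreeningRuleSet",
      rules = list(
        SC20 = quote(SC20 | SC20a),
        SC21 = quote(SC21),
        SC22 = quote(SC22),
        SC23 = quote(SC23),
        SC24 = quote(SC24),
        SC25 = quote(SC25 & SC25a),
        SC26 = quote(SC26 | SC26a | SC26b),
        SC29 = quote((SC29 | SC29a) & ((SC29.1 | SC29.2) & SC29.3)),
        SC30 = quote(SC30 & ((SC30.1 | SC30.2) & SC30.3))),
      questions = gateQuestionNames())
}

#' Compile raw gate responses into the nine screening rules
#'
#' Encodes a table of categorical gate-question answers into the
#' respondent-by-rule binary screen-in/screen-out matrix (1 = screen in).
#' The compilation is deterministic and total: "No", "Don't know" and
#' "Refused" all count as negative answers, and each rule's screen-out is
#' the complement of its screen-in clause.
#'
#' @param raw data.frame with one row per respondent and one column per
#'   gate question (see [gateQuestionNames()]); entries must be "Yes",
#'   "No", "Don't know" or "Refused".
#' @param rules a [ScreeningRuleSet-class]; the standard set by default.
#' @param group optional group labels passed through to the result.
#' @return A [ResponseMatrix-class] with 9 binary columns in rule order.
#' @examples
#' raw <- as.data.frame(setNames(
#'   rep(list("No"), 20), gateQuestionNames()))
#' raw$SC21 <- "Yes"
#' responses(encodeScreeningRules(raw))
#' @export
encodeScreeningRules <- function(raw, rules = screeningRules(), group = NULL) {
  stopifnot(is(rules, "ScreeningRuleSet"))
  raw <- as.data.frame(raw)
  missingQ <- setdiff(rules@questions, names(raw))
  if (length(missingQ))
    stop("configuration error: missing gate question column(s): ",
         paste(missingQ, collapse = ", "))
  categories <- c("Yes", "No", "Don't know", "Refused")
  yes <- new.env(parent = baseenv())
  for (q in rules@questions) {
    v <- as.character(raw[[q]])
    bad <- which(!v %in% categories)
    if (length(bad))
      stop(sprintf(
        "validation error: unknown answer category %s in column '%s', row %d",
        dQuote(v[bad[1L]]), q, bad[1L]))
    assign(q, v == "Yes", envir = yes)
  }
  out <- vapply(rules@rules,
                function(expr) as.integer(eval(expr, envir = yes)),
                integer(nrow(raw)))
  if (nrow(raw) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, names(rules@rules)))
  responseMatrix(out, group = group)
}
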