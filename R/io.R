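# Delimited-text interfaces: item parameters, latent scores, response
# matrices and the group-specific DIF report.

#' Read and write 2PL item parameters as CSV
#'
#' The file has columns item, a, b, lambda, h2 (loadings and communalities
#' are recomputed on read, not trusted).
#'
#' @param params an [ItemParameters-class].
#' @param path CSV file path.
#' @param ... passed to [utils::write.csv()] / [utils::read.csv()].
#' @return `writeItemParameters` returns `path` invisibly;
#'   `readItemParameters` returns an [ItemParameters-class].
#' @export
writeItemParameters <- function(params, path, ...) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE, ...)
  invisible(path)
}

#' @rdname writeItemParameters
#' @param D scaling constant used when reconstructing the object.
#' @export
readItemParameters <- function(path, D = 1.702, ...) {
  d <- utils::read.csv(path, comment.char = "#", ...)
  itemParameters(d$item, d$a, d$b, D)
}

#' Read a response matrix from delimited text
#'
#' @param path CSV file with one row per respondent: binary item columns
#'   plus any number of grouping columns.
#' @param items item column names; defaults to every column not named in
#'   `group`.
#' @param group optional name of the grouping column to attach; its first
#'   level (or `reference`, if given) becomes the reference group.
#' @param reference optional reference level of the grouping column.
#' @param ... passed to [utils::read.csv()].
#' @return A [ResponseMatrix-class].
#' @export
readResponseMatrix <- function(path, items = NULL, group = NULL,
                               reference = NULL, ...) {
  d <- utils::read.csv(path, comment.char = "#", ...)
  if (is.null(items)) items <- setdiff(names(d), group)
  missing <- setdiff(c(items, group), names(d))
  if (length(missing))
    stop("configuration error: column(s) not in ", path, ": ",
         paste(missing, collapse = ", "))
  g <- NULL
  if (!is.null(group)) {
    g <- factor(d[[group]])
    if (!is.null(reference)) {
      if (!reference %in% levels(g))
        stop("configuration error: reference level '", reference,
             "' not found in column '", group, "'")
      g <- stats::relevel(g, reference)
    }
  }
  responseMatrix(as.matrix(d[items]), group = g)
}

#' Write EAP scores as CSV
#'
#' @param scores a [LatentScore-class].
#' @param path CSV file path (columns: respondent, eap, psd).
#' @export
writeLatentScores <- function(scores, path) {
  d <- as.data.frame(scores)
  utils::write.csv(cbind(respondent = seq_len(nrow(d)), d), path,
                   row.names = FALSE)
  invisible(path)
}

#' Group-specific DIF report
#'
#' One row per item in the published layout: reference (a, b) always;
#' focal (a, b) only for items that displayed DIF (anchored cells are
#' empty and marked), plus the likelihood-ratio test columns.
#'
#' @param result a [DIFTestResult-class].
#' @param model the fitted DIF [GroupModel-class] (the `"model"` attribute
#'   of [testDif()]'s result by default).
#' @return data.frame: item, ref_a, ref_b, focal_a, focal_b, anchored,
#'   lr, df, p_raw, p_bh, flag.
#' @export
difReport <- function(result, model = attr(result, "model")) {
  stopifnot(is(result, "DIFTestResult"), is(model, "GroupModel"))
  items <- model@refParams@items
  tab <- result@table
  m <- match(items, tab$item)
  anchored <- items %in% result@anchors
  flagged <- !anchored & !is.na(m) & tab$flag[m]
  data.frame(item = items,
             ref_a = model@refParams@a, ref_b = model@refParams@b,
             focal_a = ifelse(flagged, model@focalParams@a, NA_real_),
             focal_b = ifelse(flagged, model@focalParams@b, NA_real_),
             anchored = anchored,
             lr = ifelse(is.na(m), NA_real_, tab$lr[m]),
             df = ifelse(is.na(m), NA_integer_, tab$df[m]),
             p_raw = ifelse(is.na(m), NA_real_, tab$p[m]),
             p_bh = ifelse(is.na(m), NA_real_, tab$p_bh[m]),
             flag = ifelse(is.na(m), FALSE, tab$flag[m]))
}
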