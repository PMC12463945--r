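## High/Middle/Low discretization of domain scores and the transaction
## encoding used for association-rule mining.

#' Per-respondent mean domain score
#'
#' @param data Likert response data.
#' @param items item codes of the domain (a single-item behavior gives the
#'   item value itself).
#' @return numeric vector of means in \[1, 5\]; NA for respondents with any
#'   missing item in the domain.
#' @export
domain_score <- function(data, items) {
  if (!length(items)) stop("empty domain")
  x <- response_matrix(data, items)
  rowMeans(x)
}

#' Categorize a mean score as Low / Middle / High
#'
#' The fixed cut rule on the 1..5 Likert mean: score < 3 is "L",
#' 3 <= score < 4 is "M", score >= 4 is "H". Boundaries: 3.0 is M, 4.0 is H.
#'
#' @param score numeric vector of mean scores in \[1, 5\].
#' @return character vector of labels in \{"L", "M", "H"\}.
#' @export
categorize_score <- function(score) {
  bad <- !is.na(score) & (score < 1 | score > 5)
  if (any(bad)) stop("scores outside [1, 5]: ",
                     paste(utils::head(score[bad]), collapse = ", "))
  out <- ifelse(score < 3, "L", ifelse(score < 4, "M", "H"))
  out[is.na(score)] <- NA_character_
  out
}

#' Build the transaction table of labeled domain levels
#'
#' Scores every domain and behavior per respondent, applies the H/M/L cut
#' rule, and encodes each respondent as a set of elements
#' \code{"DOMAIN=LEVEL"}. Respondents with a missing item in any domain are
#' dropped and enumerated in the \code{dropped} attribute, so transaction
#' building is a bijection between retained respondents and transactions.
#'
#' @param data Likert response data.
#' @param spec an [instrument_spec()].
#' @param retained optional character vector of item codes to use (e.g. the
#'   post-screening retained items); defaults to all items in the spec.
#' @return object of class \code{transactions}: character label matrix
#'   (respondents x domains), respondent ids, behavior codes.
#' @export
build_transactions <- function(data, spec, retained = NULL) {
  dom_items <- c(spec$items,
                 stats::setNames(as.list(spec$behaviors), spec$behaviors))
  if (!is.null(retained)) {
    dom_items <- lapply(dom_items, intersect, x = retained)
    # behaviors are always kept; a fully-eliminated domain would be dropped
    empty <- names(dom_items)[vapply(dom_items, length, 1L) == 0L]
    dom_items <- dom_items[setdiff(names(dom_items), empty)]
  }
  scores <- sapply(dom_items, function(it) domain_score(data, it))
  labels <- matrix(categorize_score(scores), nrow(scores), ncol(scores),
                   dimnames = dimnames(scores))
  keep <- stats::complete.cases(labels)
  ids <- if ("respondent" %in% colnames(data)) data$respondent
         else seq_len(nrow(data))
  structure(list(labels = labels[keep, , drop = FALSE],
                 respondents = ids[keep],
                 dropped = ids[!keep],
                 behaviors = intersect(spec$behaviors, colnames(labels))),
            class = "transactions")
}

#' @export
print.transactions <- function(x, ...) {
  cat(sprintf("Transaction table: %d respondents x %d domains (%d behaviors); %d dropped\n",
              nrow(x$labels), ncol(x$labels), length(x$behaviors),
              length(x$dropped)))
  lv <- table(factor(x$labels, levels = c("L", "M", "H")))
  cat("  level counts:", paste(names(lv), lv, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Recode levels of selected domains
#'
#' Deterministic relabeling, e.g. treating "M" as "L" in a domain whose
#' observed levels are only M and H. An audit log of changed counts is
#' attached as attribute \code{"recode_log"}.
#'
#' @param tt a [build_transactions()] table.
#' @param recode_map data frame (or list of 3-vectors) with columns
#'   \code{domain}, \code{from}, \code{to}.
#' @return the recoded \code{transactions} object.
#' @export
recode_levels <- function(tt, recode_map) {
  stopifnot(inherits(tt, "transactions"))
  if (is.list(recode_map) && !is.data.frame(recode_map))
    recode_map <- do.call(rbind, lapply(recode_map, function(r)
      data.frame(domain = r[1], from = r[2], to = r[3])))
  if (is.null(recode_map) || nrow(recode_map) == 0) {
    attr(tt, "recode_log") <- data.frame()
    return(tt)
  }
  log <- recode_map
  log$changed <- 0L
  for (k in seq_len(nrow(recode_map))) {
    d <- recode_map$domain[k]
    if (!d %in% colnames(tt$labels)) stop("unknown element/domain: ", d)
    hit <- tt$labels[, d] == recode_map$from[k]
    tt$labels[hit, d] <- recode_map$to[k]
    log$changed[k] <- sum(hit)
  }
  attr(tt, "recode_log") <- log
  tt
}

# respondent transactions as element sets "DOMAIN=LEVEL"
transaction_elements <- function(tt) {
  doms <- colnames(tt$labels)
  lapply(seq_len(nrow(tt$labels)), function(i)
    paste0(doms, "=", tt$labels[i, ]))
}

#' Write / read transactions as a basket file
#'
#' One respondent per line, comma-separated \code{"DOMAIN=LEVEL"} elements.
#' `write_transactions_csv()` writes the long form (respondent, element).
#'
#' @param tt a [build_transactions()] table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_basket <- function(tt, path) {
  writeLines(vapply(transaction_elements(tt), paste, "", collapse = ","), path)
  invisible(path)
}

#' @rdname write_basket
#' @export
write_transactions_csv <- function(tt, path) {
  el <- transaction_elements(tt)
  long <- data.frame(
    respondent = rep(tt$respondents, vapply(el, length, 1L)),
    element = unlist(el))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_basket
#' @param behaviors behavior codes (needed to rebuild partition metadata when
#'   reading a basket back).
#' @export
read_basket <- function(path, behaviors = paste0("BEH-", 1:8)) {
  el <- strsplit(readLines(path), ",", fixed = TRUE)
  parts <- lapply(el, function(e) {
    sp <- regmatches(e, regexpr("=[LMH]$", e))
    data.frame(domain = sub("=[LMH]$", "", e), level = sub("^=", "", sp))
  })
  doms <- unique(unlist(lapply(parts, `[[`, "domain")))
  labels <- t(vapply(parts, function(p)
    stats::setNames(p$level, p$domain)[doms], character(length(doms))))
  colnames(labels) <- doms
  structure(list(labels = labels, respondents = seq_along(el),
                 dropped = integer(0),
                 behaviors = intersect(behaviors, doms)),
            class = "transactions")
}
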