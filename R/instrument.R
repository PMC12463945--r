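#' Instrument specification for a COM-B questionnaire
#'
#' An instrument specification maps Likert items to first-order domains and
#' domains to COM-B modules (Capability, Opportunity, Motivation), and lists
#' the single-item target behaviors that form the Behavior module.
#'
#' @param domains named list: module name -> character vector of domain codes.
#'   Must contain entries for \code{"Capability"}, \code{"Motivation"} and
#'   \code{"Opportunity"}.
#' @param items named list: domain code -> character vector of item codes.
#'   Every non-behavior domain must carry at least three items, the usual
#'   minimum for a reflective latent variable.
#' @param behaviors character vector of single-item behavior codes
#'   (the items double as their own "domains").
#' @return An object of class \code{instrument_spec}: a list with elements
#'   \code{modules}, \code{domains}, \code{items}, \code{behaviors}.
#' @seealso [default_instrument()] for the instrument used throughout the
#'   package's worked examples.
#' @export
instrument_spec <- function(domains, items, behaviors) {
  stopifnot(is.list(domains), is.list(items), is.character(behaviors))
  needed <- c("Capability", "Motivation", "Opportunity")
  if (!all(needed %in% names(domains)))
    stop("'domains' must have entries for Capability, Motivation and Opportunity")
  all_dom <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(all_dom)) stop("duplicated domain codes across modules")
  if (!setequal(names(items), all_dom))
    stop("'items' must define exactly the domains listed in 'domains'")
  short <- names(items)[vapply(items, length, 1L) < 3L]
  if (length(short))
    stop("every non-behavior domain needs >= 3 items; too few in: ",
         paste(short, collapse = ", "))
  all_items <- c(unlist(items, use.names = FALSE), behaviors)
  if (anyDuplicated(all_items))
    stop("every item must belong to exactly one domain; duplicates: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  structure(
    list(modules = c(needed, "Behavior"),
         domains = domains[needed],
         items = items,
         behaviors = behaviors),
    class = "instrument_spec")
}

#' Default COM-B instrument (retained structure)
#'
#' The instrument with the retained post-screening structure: three Capability
#' domains (behavioral regulation BR, decision making DM, knowledge and skills
#' KS) of three items each; seven Motivation domains (SR, OP, BCO, REI, EM,
#' INT, BCA) of three items each; the five occupational-health-culture
#' Opportunity domains values (VAL, 3 items), leadership support (LS, 5),
#' policies and norms (PN, 5), physical environment (PE, 4), employee
#' involvement (EI, 4); and eight single-item risk-coping behaviors
#' BEH-1..BEH-8 (medical insurance, protective equipment, ventilation,
#' physical examination, avoiding rest/eating on site, social relationships,
#' avoiding musculoskeletal strain, avoiding heat/cold illness).
#'
#' @return An [instrument_spec()] with 15 non-behavior domains (9 Capability
#'   items, 21 Motivation items, 21 Opportunity items) and 8 behaviors.
#' @export
default_instrument <- function() {
  instrument_spec(
    domains = list(
      Capability  = c("BR", "DM", "KS"),
      Motivation  = c("SR", "OP", "BCO", "REI", "EM", "INT", "BCA"),
      Opportunity = c("VAL", "LS", "PN", "PE", "EI")),
    items = list(
      BR  = c("BR1", "BR2", "BR4"),
      DM  = c("DM2", "DM4", "DM3"),
      KS  = c("KS4", "KS2", "KS1"),
      SR  = c("SR3", "SR1", "SR2"),
      OP  = c("OP1", "OP2", "OP3"),
      BCO = c("BCO1", "BCO3", "BCO2"),
      REI = c("REI3", "REI1", "REI2"),
      EM  = c("EM3", "EM2", "EM1"),
      INT = c("INT1", "INT2", "INT3"),
      BCA = c("BCA1", "BCA2", "BCA3"),
      VAL = paste0("VAL", 1:3),
      LS  = paste0("LS", 1:5),
      PN  = paste0("PN", 1:5),
      PE  = paste0("PE", 1:4),
      EI  = paste0("EI", 1:4)),
    behaviors = paste0("BEH-", 1:8))
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("COM-B instrument specification\n")
  for (m in setdiff(x$modules, "Behavior")) {
    doms <- x$domains[[m]]
    k <- vapply(x$items[doms], length, 1L)
    cat(sprintf("  %-11s %d domains, %d items (%s)\n", m, length(doms),
                sum(k), paste(sprintf("%s:%d", doms, k), collapse = " ")))
  }
  cat(sprintf("  %-11s %d single-item behaviors\n", "Behavior",
              length(x$behaviors)))
  invisible(x)
}

# all measured columns, behaviors last
instrument_items <- function(spec, include_behaviors = TRUE) {
  out <- unlist(spec$items[unlist(spec$domains, use.names = FALSE)],
                use.names = FALSE)
  if (include_behaviors) out <- c(out, spec$behaviors)
  out
}

# named vector item -> domain (behavior items map to themselves)
item_domain_map <- function(spec) {
  m <- rep(names(spec$items), vapply(spec$items, length, 1L))
  names(m) <- unlist(spec$items, use.names = FALSE)
  c(m, stats::setNames(spec$behaviors, spec$behaviors))
}

# named vector domain -> module (behaviors -> "Behavior")
domain_module_map <- function(spec) {
  m <- rep(names(spec$domains), vapply(spec$domains, length, 1L))
  names(m) <- unlist(spec$domains, use.names = FALSE)
  c(m, stats::setNames(rep("Behavior", length(spec$behaviors)), spec$behaviors))
}

#' Read / write an instrument specification as YAML
#'
#' @param spec an [instrument_spec()].
#' @param path file path.
#' @return `write_instrument()` returns `path` invisibly; `read_instrument()`
#'   returns an [instrument_spec()].
#' @export
write_instrument <- function(spec, path) {
  stopifnot(inherits(spec, "instrument_spec"))
  yaml::write_yaml(list(domains = spec$domains,
                        items = spec$items,
                        behaviors = spec$behaviors), path)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  y <- yaml::read_yaml(path)
  instrument_spec(domains = lapply(y$domains, as.character),
                  items = lapply(y$items, as.character),
                  behaviors = as.character(y$behaviors))
}
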