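## From-scratch Apriori frequent-itemset mining and association-rule
## generation with Support / Confidence / Lift, behavior-partitioned
## filtering, top-N strong rules per partition, and domain-frequency
## profiling. Support is always computed over all N transactions.

# logical incidence matrix N x vocabulary from a transactions object
incidence_matrix <- function(tt) {
  stopifnot(inherits(tt, "transactions"))
  doms <- colnames(tt$labels)
  vocab <- as.vector(t(outer(doms, c("L", "M", "H"), paste, sep = "=")))
  M <- matrix(FALSE, nrow(tt$labels), length(vocab),
              dimnames = list(NULL, vocab))
  for (j in seq_along(doms))
    M[cbind(seq_len(nrow(M)),
            match(paste0(doms[j], "=", tt$labels[, j]), vocab))] <- TRUE
  M[, colSums(M) > 0, drop = FALSE]
}

itemset_key <- function(items) paste(sort(items), collapse = "\r")

#' Apriori frequent-itemset mining
#'
#' Level-wise candidate generation with subset pruning: all itemsets whose
#' support (proportion of transactions containing every element) is at least
#' \code{min_support}.
#'
#' @param tt a [build_transactions()] table, or a logical incidence matrix
#'   (transactions x elements).
#' @param min_support minimum support proportion in (0, 1].
#' @param max_size optional cap on itemset size (default unlimited).
#' @return data frame of class \code{itemsets}: list-column \code{items}
#'   (sorted element vectors), \code{size}, \code{support}.
#' @export
apriori_frequent_itemsets <- function(tt, min_support = 0.05,
                                      max_size = Inf) {
  M <- if (is.matrix(tt)) tt else incidence_matrix(tt)
  if (min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]")
  if (nrow(M) == 0) stop("empty transaction table")
  N <- nrow(M)
  vocab <- colnames(M)
  supp1 <- colSums(M) / N
  keep <- which(supp1 >= min_support)

  # level-wise growth over sorted column-index sets; each itemset carries its
  # transaction indicator so a candidate's support is one vectorized AND.
  # Joining two frequent (k-1)-sets that share their k-2 prefix generates
  # every frequent k-set exactly once (its two subsets dropping the last and
  # second-to-last element are frequent and share that prefix).
  sets <- lapply(keep, identity)
  ind <- M[, keep, drop = FALSE]
  supp <- unname(supp1[keep])
  out_items <- sets
  out_supp <- supp
  k <- 1L
  while (length(sets) > 1L && k < max_size) {
    k <- k + 1L
    prefix <- vapply(sets, function(s) paste(s[-(k - 1L)], collapse = " "), "")
    new_sets <- list(); new_ind <- list(); new_supp <- numeric()
    for (g in split(seq_along(sets), prefix)) {
      if (length(g) < 2L) next
      g <- g[order(vapply(sets[g], function(s) s[k - 1L], 1L))]
      for (a in seq_len(length(g) - 1L)) {
        va <- ind[, g[a]]
        for (b in seq.int(a + 1L, length(g))) {
          v <- va & ind[, g[b]]
          s <- sum(v) / N
          if (s >= min_support) {
            new_sets[[length(new_sets) + 1L]] <-
              c(sets[[g[a]]], sets[[g[b]]][k - 1L])
            new_ind[[length(new_ind) + 1L]] <- v
            new_supp <- c(new_supp, s)
          }
        }
      }
    }
    if (!length(new_sets)) break
    sets <- new_sets
    ind <- matrix(unlist(new_ind), N, length(new_ind))
    supp <- new_supp
    out_items <- c(out_items, sets)
    out_supp <- c(out_supp, supp)
  }
  out <- data.frame(size = vapply(out_items, length, 1L),
                    support = out_supp)
  out$items <- lapply(out_items, function(s) sort(vocab[s]))
  class(out) <- c("itemsets", "data.frame")
  out
}

#' Generate association rules with a single behavior consequent
#'
#' For every frequent itemset containing exactly one consequent element Y and
#' a non-empty antecedent X, emits the rule X -> Y with
#' \code{support = P(X,Y)}, \code{confidence = P(X,Y)/P(X)} and
#' \code{lift = confidence / P(Y)}. Rules are kept only when all three
#' thresholds hold simultaneously; the lift threshold is strict
#' (\code{lift > min_lift}), the support and confidence thresholds are
#' minima (\code{>=}).
#'
#' @param itemsets [apriori_frequent_itemsets()] output (complete for the
#'   support threshold in use).
#' @param tt the transaction table the itemsets were mined from (used for
#'   marginal consequent supports).
#' @param consequents character vector of allowed consequent elements
#'   (typically the behavior elements at levels H and L).
#' @param min_confidence,min_lift thresholds (defaults 0.5 and 2).
#' @param restrict_antecedents if TRUE (default), antecedents may not contain
#'   behavior-consequent elements, mirroring an analysis whose rules predict
#'   one behavior from the non-behavior domains.
#' @return data frame of class \code{assoc_rules}: \code{antecedent}
#'   (list-column), \code{consequent}, \code{support}, \code{confidence},
#'   \code{lift}.
#' @export
generate_rules <- function(itemsets, tt, consequents,
                           min_confidence = 0.5, min_lift = 2,
                           restrict_antecedents = TRUE) {
  M <- if (is.matrix(tt)) tt else incidence_matrix(tt)
  N <- nrow(M)
  marg <- colSums(M) / N
  ants <- vector("list", nrow(itemsets))
  cons <- character(nrow(itemsets)); supp <- numeric(nrow(itemsets))
  j <- 0L
  for (r in seq_len(nrow(itemsets))) {
    s <- itemsets$items[[r]]
    if (length(s) < 2L) next
    cons_in <- s[s %in% consequents]
    if (length(cons_in) != 1L) next
    X <- s[s != cons_in]
    if (restrict_antecedents && any(X %in% consequents)) next
    j <- j + 1L
    ants[[j]] <- X; cons[j] <- cons_in; supp[j] <- itemsets$support[r]
  }
  length(ants) <- j; cons <- cons[seq_len(j)]; supp <- supp[seq_len(j)]
  # antecedent supports in one keyed match; subsets of a frequent set are
  # themselves frequent, so every antecedent is present
  keys <- vapply(itemsets$items, itemset_key, "")
  sX <- itemsets$support[match(vapply(ants, itemset_key, ""), keys)]
  conf <- supp / sX
  lift <- conf / unname(marg[cons])
  ok <- conf >= min_confidence & lift > min_lift
  out <- data.frame(consequent = cons[ok], support = supp[ok],
                    confidence = conf[ok], lift = lift[ok])
  out$antecedent <- ants[ok]
  rownames(out) <- NULL
  class(out) <- c("assoc_rules", "data.frame")
  out
}

#' Mine association rules from a transaction table
#'
#' Convenience wrapper: Apriori frequent itemsets at \code{min_support}, then
#' [generate_rules()] with the behavior elements at the given levels as
#' consequents.
#'
#' @inheritParams apriori_frequent_itemsets
#' @inheritParams generate_rules
#' @param levels consequent levels (default H, M and L; M-consequent rules
#'   are removed later during partitioning).
#' @return an \code{assoc_rules} data frame.
#' @export
mine_rules <- function(tt, min_support = 0.05, min_confidence = 0.5,
                       min_lift = 2, levels = c("H", "M", "L"),
                       max_size = Inf, restrict_antecedents = TRUE) {
  cons <- as.vector(outer(tt$behaviors, levels, paste, sep = "="))
  fi <- apriori_frequent_itemsets(tt, min_support, max_size)
  generate_rules(fi, tt, cons, min_confidence, min_lift,
                 restrict_antecedents)
}

#' Partition rules by behavior consequent and eliminate middle levels
#'
#' Rules with an M-level consequent are dropped first; the remainder are
#' grouped into (behavior x level) partitions such as \code{"BEH-1=H"}.
#' Within each partition, rules whose antecedent contains any M-level element
#' are removed, unless that element's domain is listed in the partition's
#' exception set (used when a partition would otherwise retain too few rules,
#' keeping the domain whose highest observed score is M).
#'
#' @param rules an \code{assoc_rules} data frame.
#' @param drop_middle if FALSE, only partitioning is performed.
#' @param exceptions named list: partition key -> character vector of domains
#'   whose M level is retained in that partition.
#' @param behaviors behavior codes defining the admissible partition keys.
#' @return object of class \code{rule_partitions}: list of partitions, each
#'   with \code{key}, \code{rules}, counts before/after filtering.
#' @export
partition_and_filter <- function(rules, drop_middle = TRUE,
                                 exceptions = list(),
                                 behaviors = paste0("BEH-", 1:8)) {
  valid_keys <- as.vector(outer(behaviors, c("H", "L"), paste, sep = "="))
  bad <- setdiff(names(exceptions), valid_keys)
  if (length(bad)) stop("exception references unknown partition: ",
                        paste(bad, collapse = ", "))
  rules <- rules[!grepl("=M$", rules$consequent), , drop = FALSE]
  parts <- lapply(unique(rules$consequent), function(key) {
    rs <- rules[rules$consequent == key, , drop = FALSE]
    before <- nrow(rs)
    if (drop_middle) {
      allowed <- exceptions[[key]]
      keep <- vapply(rs$antecedent, function(a) {
        mid <- a[grepl("=M$", a)]
        !length(mid) || all(sub("=M$", "", mid) %in% allowed)
      }, logical(1))
      rs <- rs[keep, , drop = FALSE]
    }
    list(key = key, rules = rs, n_before = before, n_after = nrow(rs))
  })
  names(parts) <- vapply(parts, `[[`, "", "key")
  structure(parts, class = "rule_partitions")
}

#' @export
print.rule_partitions <- function(x, ...) {
  cat(sprintf("Rule partitions: %d\n", length(x)))
  for (p in x)
    cat(sprintf("  %-10s %5d rules (%d before middle-level filtering)%s\n",
                p$key, p$n_after, p$n_before,
                if (!is.null(p$strong)) sprintf(", %d strong", nrow(p$strong))
                else ""))
  invisible(x)
}

# full deterministic sort key: lift desc, confidence desc, support desc,
# antecedent lexicographic asc
rule_order <- function(rules) {
  ant <- vapply(rules$antecedent, paste, "", collapse = ",")
  order(-rules$lift, -rules$confidence, -rules$support, ant)
}

#' Extract the top-N strong rules of each partition by lift
#'
#' Rules are sorted by lift (descending) with ties broken by confidence,
#' support, then the antecedent string; the first \code{n} are the
#' partition's strong rules. Boundary ties resolved by the tie-break are
#' flagged in \code{tie_at_boundary}.
#'
#' @param partitions a [partition_and_filter()] result.
#' @param n number of strong rules per partition (default 10).
#' @return the partitions, each with added elements \code{strong} (sorted
#'   rule data frame) and \code{tie_at_boundary}.
#' @export
top_strong_rules <- function(partitions, n = 10L) {
  stopifnot(inherits(partitions, "rule_partitions"))
  out <- lapply(partitions, function(p) {
    rs <- p$rules[rule_order(p$rules), , drop = FALSE]
    k <- min(n, nrow(rs))
    p$strong <- rs[seq_len(k), , drop = FALSE]
    p$tie_at_boundary <- k < nrow(rs) && k > 0 &&
      rs$lift[k] == rs$lift[k + 1L]
    p
  })
  structure(out, class = "rule_partitions")
}

#' Domain-frequency profile of a partition's strong rules
#'
#' Counts how often each domain (antecedent element stripped of its level)
#' appears across the partition's strong rules, flagging high-frequency
#' domains at \code{threshold}.
#'
#' @param partition one element of a [top_strong_rules()] result (or a
#'   \code{rule_partitions} object, profiled partition-wise).
#' @param threshold count at which a domain is flagged (default 5).
#' @return data frame \code{domain}, \code{count}, \code{flagged} (or a named
#'   list of such, one per partition).
#' @export
domain_frequency <- function(partition, threshold = 5L) {
  if (inherits(partition, "rule_partitions"))
    return(lapply(partition, domain_frequency, threshold = threshold))
  rules <- partition$strong
  if (is.null(rules)) rules <- partition$rules
  doms <- sub("=[LMH]$", "", unlist(rules$antecedent))
  counts <- sort(table(doms), decreasing = TRUE)
  data.frame(domain = as.character(names(counts)),
             count = as.integer(counts),
             flagged = as.integer(counts) >= threshold, row.names = NULL)
}

#' Write mined rules as CSV
#'
#' @param partitions a [top_strong_rules()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rules_csv <- function(partitions, path) {
  rows <- lapply(partitions, function(p) {
    rs <- p$rules
    if (!nrow(rs)) return(NULL)
    strong_keys <- if (!is.null(p$strong))
      vapply(p$strong$antecedent, paste, "", collapse = "|") else character(0)
    data.frame(
      antecedent = vapply(rs$antecedent, paste, "", collapse = "|"),
      consequent = rs$consequent, support = rs$support,
      confidence = rs$confidence, lift = rs$lift, partition = p$key,
      strong = vapply(rs$antecedent, paste, "", collapse = "|") %in% strong_keys)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
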