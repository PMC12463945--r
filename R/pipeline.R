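## Configuration, orchestration and report assembly for the end-to-end
## pipeline: simulate -> psychometrics -> sem -> categorize -> mine -> report.

#' Pipeline configuration
#'
#' Collects every stage threshold with the conventional defaults: item-total
#' 0.5, loading 0.5, cross-loading 0.5, eigenvalue 1.0, support 0.05,
#' confidence 0.5, lift 2.0, top-N 10, domain-frequency threshold 5,
#' bootstrap B 5000.
#'
#' @param out_dir output directory (created if needed).
#' @param responses optional path to a responses CSV; when NULL the simulate
#'   stage generates data.
#' @param spec an [instrument_spec()].
#' @param n respondents to simulate when no responses are supplied.
#' @param seed master integer seed; all stage randomness derives from it.
#' @param stages character vector of stages to run.
#' @param bootstrap_B mediation bootstrap resamples (0 disables mediation).
#' @param item_total,loading,cross,eigen,support,confidence,lift,top_n,freq_threshold
#'   stage thresholds, defaulting as above.
#' @param recode optional recode map for [recode_levels()].
#' @param exceptions per-partition middle-level exception list for
#'   [partition_and_filter()].
#' @return a validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            responses = NULL,
                            spec = default_instrument(),
                            n = 484L,
                            seed = 1L,
                            stages = c("simulate", "psychometrics", "sem",
                                       "categorize", "mine", "report"),
                            bootstrap_B = 5000L,
                            item_total = 0.5, loading = 0.5, cross = 0.5,
                            eigen = 1.0, support = 0.05, confidence = 0.5,
                            lift = 2.0, top_n = 10L, freq_threshold = 5L,
                            recode = NULL, exceptions = list()) {
  cfg <- as.list(environment())
  if (cfg$support <= 0 || cfg$support > 1) stop("support must be in (0, 1]")
  if (cfg$confidence <= 0 || cfg$confidence > 1)
    stop("confidence must be in (0, 1]")
  if (cfg$lift <= 0) stop("lift must be positive")
  if (cfg$n < 1) stop("n must be >= 1")
  if (is.null(cfg$responses) && !"simulate" %in% cfg$stages)
    stop("either supply 'responses' or enable the simulate stage")
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order, writes every stage's outputs under
#' \code{config$out_dir}, and records a machine-readable manifest
#' (stage, outputs, MD5 hashes, elapsed seconds, warnings) as
#' \code{manifest.json} alongside the resolved configuration.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list of stage records).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  state <- new.env(parent = emptyenv())
  record <- function(stage, files, t0, warnings = character()) {
    manifest[[stage]] <<- list(
      stage = stage, outputs = basename(files),
      md5 = unname(tools::md5sum(files)),
      elapsed = round(as.numeric(Sys.time()) - t0, 3),
      warnings = warnings)
  }
  runs <- function(s) s %in% config$stages
  spec <- config$spec

  ## simulate ------------------------------------------------------------
  if (runs("simulate")) {
    t0 <- as.numeric(Sys.time())
    params <- ground_truth(spec)
    state$data <- generate_responses(params, config$n, seed = config$seed)
    f <- file.path(config$out_dir, "responses.csv")
    write_responses(state$data, f)
    stage_log("simulate", "n = %d respondents, seed %d", config$n, config$seed)
    record("simulate", f, t0)
  } else {
    if (is.null(config$responses) || !file.exists(config$responses))
      stop("stage 'simulate' disabled and responses file missing: ",
           config$responses)
    state$data <- read_responses(config$responses, spec)
  }

  ## psychometrics -------------------------------------------------------
  if (runs("psychometrics")) {
    t0 <- as.numeric(Sys.time())
    half1 <- split_half(state$data, "first")
    rel <- lapply(setdiff(spec$modules, "Behavior"), function(mod) {
      items <- unlist(spec$items[spec$domains[[mod]]], use.names = FALSE)
      adequacy <- list(kmo = kmo(half1, items)$kmo,
                       bartlett = bartlett_sphericity(half1, items))
      sol <- efa_pca_varimax(half1, items, config$eigen)
      it <- unlist(lapply(spec$domains[[mod]], function(d)
        corrected_item_total(half1, spec$items[[d]])))
      screen <- apply_item_retention_rules(sol, it,
                                           config$item_total, config$loading,
                                           config$cross)
      rv <- reliability_validity(state$data, spec, mod)
      list(module = mod, adequacy = adequacy, efa = sol,
           screening = screen, reliability = rv)
    })
    names(rel) <- setdiff(spec$modules, "Behavior")
    state$psych <- rel
    f <- file.path(config$out_dir, "reliability.csv")
    utils::write.csv(do.call(rbind, lapply(rel, function(r) r$reliability$table)),
                     f, row.names = FALSE)
    f2 <- file.path(config$out_dir, "screening.csv")
    utils::write.csv(do.call(rbind, lapply(rel, function(r)
      as.data.frame(r$screening))), f2, row.names = FALSE)
    stage_log("psychometrics", "%d modules screened", length(rel))
    record("psychometrics", c(f, f2), t0)
  }

  ## sem -----------------------------------------------------------------
  if (runs("sem")) {
    t0 <- as.numeric(Sys.time())
    model <- comb_model(spec)
    fit <- sem_fit(model, state$data)
    state$sem <- fit
    idx <- fit_indices(fit)
    f <- file.path(config$out_dir, "fit_indices.json")
    jsonlite::write_json(idx[c("chi2", "df", "chi2_df", "GFI", "AGFI",
                               "RMSEA", "SRMR", "NFI", "TLI", "CFI")],
                         f, auto_unbox = TRUE, digits = NA)
    f2 <- file.path(config$out_dir, "parameters.csv")
    utils::write.csv(summary(fit)$parameters, f2, row.names = FALSE)
    files <- c(f, f2)
    if (config$bootstrap_B >= 100) {
      state$mediation <- list(
        capability = bootstrap_mediation(model, state$data, "Capability",
                                         "Motivation", "Behavior",
                                         B = config$bootstrap_B,
                                         seed = config$seed + 1L),
        opportunity = bootstrap_mediation(model, state$data, "Opportunity",
                                          "Motivation", "Behavior",
                                          B = config$bootstrap_B,
                                          seed = config$seed + 2L))
      f3 <- file.path(config$out_dir, "mediation.csv")
      utils::write.csv(do.call(rbind, lapply(state$mediation, mediation_table)),
                       f3, row.names = FALSE)
      files <- c(files, f3)
    }
    stage_log("sem", "F_ML = %.4f, chi2/df = %.3f", fit$F, idx$chi2_df)
    record("sem", files, t0,
           warnings = if (length(fit$heywood))
             paste("Heywood:", paste(fit$heywood, collapse = ",")) else character())
  }

  ## categorize ----------------------------------------------------------
  if (runs("categorize")) {
    t0 <- as.numeric(Sys.time())
    tt <- build_transactions(state$data, spec)
    if (!is.null(config$recode)) tt <- recode_levels(tt, config$recode)
    state$transactions <- tt
    f <- file.path(config$out_dir, "basket.txt")
    write_basket(tt, f)
    f2 <- file.path(config$out_dir, "transactions.csv")
    write_transactions_csv(tt, f2)
    stage_log("categorize", "%d transactions (%d respondents dropped)",
              nrow(tt$labels), length(tt$dropped))
    record("categorize", c(f, f2), t0)
  }

  ## mine ----------------------------------------------------------------
  if (runs("mine")) {
    t0 <- as.numeric(Sys.time())
    rules <- mine_rules(state$transactions, config$support, config$confidence,
                        config$lift)
    parts <- partition_and_filter(rules, exceptions = config$exceptions,
                                  behaviors = state$transactions$behaviors)
    parts <- top_strong_rules(parts, config$top_n)
    state$partitions <- parts
    state$freq <- domain_frequency(parts, config$freq_threshold)
    f <- file.path(config$out_dir, "rules.csv")
    write_rules_csv(parts, f)
    f2 <- file.path(config$out_dir, "domain_frequency.csv")
    utils::write.csv(do.call(rbind, Map(function(k, d)
      if (nrow(d)) cbind(partition = k, d) else NULL,
      names(state$freq), state$freq)),
      f2, row.names = FALSE)
    stage_log("mine", "%d rules across %d partitions", nrow(rules),
              length(parts))
    record("mine", c(f, f2), t0)
  }

  ## report --------------------------------------------------------------
  if (runs("report")) {
    t0 <- as.numeric(Sys.time())
    rep <- render_report(state)
    f <- file.path(config$out_dir, "report.md")
    writeLines(rep$markdown, f)
    f2 <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(rep$json, f2, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    stage_log("report", "%d warnings", rep$n_warnings)
    record("report", c(f, f2), t0, warnings = rep$gaps)
  }

  cfg_out <- config
  cfg_out$spec <- NULL
  jsonlite::write_json(cfg_out[!vapply(cfg_out, is.null, TRUE)],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(unname(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Assemble the analysis report from pipeline stage outputs
#'
#' Builds a Markdown document and a JSON-ready list covering whichever stages
#' have produced output: reliability/validity tables, fit indices, the
#' mediation table, and per-partition strong rules with domain frequencies.
#' Missing stages are reported as explicit gaps rather than errors.
#'
#' @param state environment or list with any of \code{psych}, \code{sem},
#'   \code{mediation}, \code{partitions}, \code{freq}.
#' @return list with \code{markdown} (character lines), \code{json},
#'   \code{gaps}, \code{n_warnings}.
#' @export
render_report <- function(state) {
  if (is.environment(state)) state <- as.list(state)
  md <- c("# COM-B analysis report", "")
  json <- list()
  gaps <- character()

  if (!is.null(state$psych)) {
    md <- c(md, "## Reliability and validity", "")
    for (r in state$psych) {
      tab <- r$reliability$table
      md <- c(md, sprintf("### %s (KMO = %.3f, Bartlett p = %.3g)",
                          r$module, r$adequacy$kmo, r$adequacy$bartlett$p.value),
              "", "domain | k | alpha | CR | AVE | sqrt(AVE)",
              "---|---|---|---|---|---",
              sprintf("%s | %d | %.3f | %.3f | %.3f | %.3f",
                      tab$domain, tab$k, tab$alpha, tab$cr, tab$ave,
                      tab$sqrt_ave), "")
    }
    json$reliability <- lapply(state$psych, function(r) r$reliability$table)
  } else gaps <- c(gaps, "psychometrics stage not run: reliability tables omitted")

  if (!is.null(state$sem)) {
    idx <- fit_indices(state$sem)
    md <- c(md, "## Structural model", "",
            sprintf("chi2 = %.3f, df = %d, chi2/df = %.3f, GFI = %.3f, AGFI = %.3f, RMSEA = %.3f, SRMR = %.3f, NFI = %.3f, TLI = %.3f, CFI = %.3f",
                    idx$chi2, idx$df, idx$chi2_df, idx$GFI, idx$AGFI,
                    idx$RMSEA, idx$SRMR, idx$NFI, idx$TLI, idx$CFI), "")
    json$fit_indices <- idx[c("chi2", "df", "chi2_df", "GFI", "AGFI", "RMSEA",
                              "SRMR", "NFI", "TLI", "CFI")]
  } else gaps <- c(gaps, "sem stage not run: fit indices omitted")

  if (!is.null(state$mediation)) {
    tab <- do.call(rbind, lapply(state$mediation, mediation_table))
    tab <- tab[tab$effect != "total", ]  # direct + indirect rows per path
    md <- c(md, "## Mediation tests", "",
            "path | effect | value | SE | bias-corrected 95% CI | percentile 95% CI | p",
            "---|---|---|---|---|---|---",
            sprintf("%s | %s | %.3f | %.3f | (%.3f, %.3f) | (%.3f, %.3f) | %.3f",
                    tab$path, tab$effect, tab$value, tab$se, tab$bc_lower,
                    tab$bc_upper, tab$perc_lower, tab$perc_upper, tab$p),
            "",
            sprintf("- %s mediation for %s",
                    vapply(state$mediation, `[[`, "", "classification"),
                    vapply(state$mediation, `[[`, "", "x")), "")
    json$mediation <- tab
  } else gaps <- c(gaps, "mediation not run: mediation table omitted")

  if (!is.null(state$partitions)) {
    md <- c(md, "## Strong association rules", "")
    for (p in state$partitions) {
      md <- c(md, sprintf("### %s (%d rules after filtering)", p$key, p$n_after))
      if (is.null(p$strong) || !nrow(p$strong)) {
        md <- c(md, "", "no strong rules", "")
        next
      }
      md <- c(md, "", "antecedent | support | confidence | lift",
              "---|---|---|---",
              sprintf("%s | %.3f | %.3f | %.2f",
                      vapply(p$strong$antecedent, paste, "", collapse = ", "),
                      p$strong$support, p$strong$confidence, p$strong$lift), "")
      if (!is.null(state$freq[[p$key]])) {
        fl <- state$freq[[p$key]]
        hot <- fl$domain[fl$flagged]
        md <- c(md, sprintf("High-frequency domains (>= threshold): %s",
                            if (length(hot)) paste(hot, collapse = ", ")
                            else "none"), "")
      }
    }
    json$partitions <- lapply(state$partitions, function(p)
      list(key = p$key, n_rules = p$n_after,
           strong = if (!is.null(p$strong) && nrow(p$strong))
             data.frame(antecedent = vapply(p$strong$antecedent, paste, "",
                                            collapse = ","),
                        support = p$strong$support,
                        confidence = p$strong$confidence,
                        lift = p$strong$lift) else NULL))
  } else gaps <- c(gaps, "mine stage not run: rule partitions omitted")

  if (length(gaps)) md <- c(md, "## Gaps", "", paste("-", gaps), "")
  list(markdown = md, json = json, gaps = gaps, n_warnings = length(gaps))
}
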