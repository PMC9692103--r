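# JSON rule/ruleset formalism, decision evaluation, and threshold derivation
# (accept-percentile and quantile-grid search).

RULE_OPS <- c("<", "<=", ">", ">=", "==")

#' Construct a threshold rule for one SQI
#'
#' A rule is an ordered list of boundaries, each `(op, value, decision)`;
#' boundaries are evaluated in order, the first matching boundary's decision
#' wins, and a value matching no boundary is accepted. `NA` values take
#' `na_decision` (default reject: quality-control conservatism).
#'
#' @param sqi_name SQI column name the rule addresses.
#' @param boundaries list of lists with fields `op` (one of `<`, `<=`, `>`,
#'   `>=`, `==`), `value` (finite numeric), `decision` (`"accept"` or
#'   `"reject"`).
#' @param na_decision decision for missing values.
#' @return object of class `sqi_rule`.
#' @export
sqi_rule <- function(sqi_name, boundaries, na_decision = c("reject", "accept")) {
  na_decision <- match.arg(na_decision)
  if (!length(boundaries)) stop_config("rule '%s': boundaries must be non-empty",
                                       sqi_name)
  for (i in seq_along(boundaries)) {
    b <- boundaries[[i]]
    if (!is.list(b) || is.null(b$op) || is.null(b$value) || is.null(b$decision)) {
      stop_config("rule '%s' boundary %d: need op, value, decision", sqi_name, i)
    }
    if (!b$op %in% RULE_OPS) {
      stop_config("rule '%s' boundary %d: unknown operator '%s'", sqi_name, i, b$op)
    }
    if (!is.numeric(b$value) || !is.finite(b$value)) {
      stop_config("rule '%s' boundary %d: threshold must be finite", sqi_name, i)
    }
    if (!b$decision %in% c("accept", "reject")) {
      stop_config("rule '%s' boundary %d: decision must be accept/reject",
                  sqi_name, i)
    }
  }
  structure(list(sqi_name = sqi_name, boundaries = boundaries,
                 na_decision = na_decision), class = "sqi_rule")
}

#' Construct an ordered ruleset
#'
#' @param rules named list of [sqi_rule()] objects (names = SQI names).
#' @param order character vector giving evaluation order; default the list
#'   order. Combination semantics are `all_accept`: every rule must accept,
#'   the first rejecting rule short-circuits.
#' @return object of class `sqi_ruleset`.
#' @export
sqi_ruleset <- function(rules, order = NULL) {
  if (!length(rules)) stop_config("ruleset must contain at least one rule")
  nm <- vapply(rules, `[[`, "", "sqi_name")
  names(rules) <- nm
  if (is.null(order)) order <- nm
  missing <- setdiff(order, nm)
  if (length(missing)) {
    stop_config("ruleset order references undefined rule(s): %s",
                paste(missing, collapse = ", "))
  }
  structure(list(rules = rules, order = order, combination = "all_accept"),
            class = "sqi_ruleset")
}

#' Parse a ruleset from JSON text or file
#'
#' Schema: `{"rules": {"<sqi_name>": {"boundaries": [{"op": ">=", "value":
#' 3.0, "decision": "reject"}, ...], "na_decision": "reject"}, ...},
#' "order": ["<sqi_name>", ...]}`. Unknown operators, empty rule objects and
#' order entries without a rule are configuration errors naming the
#' offending node.
#'
#' @param json_text JSON string, or a path to a JSON file.
#' @return an [sqi_ruleset()].
#' @export
parse_ruleset <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{]", json_text) &&
      file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e) stop_config("ruleset JSON parse error: %s",
                                                  conditionMessage(e)))
  if (is.null(obj$rules) || !length(obj$rules)) {
    stop_config("ruleset JSON: 'rules' object is missing or empty")
  }
  rules <- lapply(names(obj$rules), function(nm) {
    node <- obj$rules[[nm]]
    if (is.null(node$boundaries) || !length(node$boundaries)) {
      stop_config("ruleset JSON: rules.%s.boundaries missing or empty", nm)
    }
    bounds <- lapply(seq_along(node$boundaries), function(i) {
      b <- node$boundaries[[i]]
      if (is.null(b$op) || is.null(b$value) || is.null(b$decision)) {
        stop_config("ruleset JSON: rules.%s.boundaries[%d] needs op/value/decision",
                    nm, i)
      }
      list(op = b$op, value = as.numeric(b$value), decision = b$decision)
    })
    sqi_rule(nm, bounds, na_decision = node$na_decision %||% "reject")
  })
  names(rules) <- names(obj$rules)
  order <- if (!is.null(obj$order)) unlist(obj$order) else names(rules)
  sqi_ruleset(rules, order)
}

#' Serialize a ruleset to JSON
#'
#' Inverse of [parse_ruleset()]: parse-serialize-parse round-trips to an
#' equal structure.
#'
#' @param ruleset an [sqi_ruleset()].
#' @param path optional file to write.
#' @return JSON string (invisibly when `path` is given).
#' @export
serialize_ruleset <- function(ruleset, path = NULL) {
  rules <- lapply(ruleset$rules, function(r) {
    list(boundaries = lapply(r$boundaries, function(b) {
      list(op = jsonlite::unbox(b$op), value = jsonlite::unbox(b$value),
           decision = jsonlite::unbox(b$decision))
    }), na_decision = jsonlite::unbox(r$na_decision))
  })
  txt <- jsonlite::toJSON(list(rules = rules, order = ruleset$order),
                          pretty = TRUE, auto_unbox = FALSE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Apply one rule to one value
#'
#' @param rule an [sqi_rule()].
#' @param value numeric scalar or `NA`.
#' @return `"accept"` or `"reject"`.
#' @export
apply_rule <- function(rule, value) {
  if (is.null(value) || length(value) != 1L || is.na(value)) {
    return(rule$na_decision)
  }
  for (b in rule$boundaries) {
    hit <- switch(b$op,
                  "<" = value < b$value,
                  "<=" = value <= b$value,
                  ">" = value > b$value,
                  ">=" = value >= b$value,
                  "==" = value == b$value)
    if (isTRUE(hit)) return(b$decision)
  }
  "accept"
}

#' Apply a ruleset to one SQI row
#'
#' Rules run in the ruleset order; the first rejecting rule short-circuits
#' and is recorded as `triggered_rule`; a row every rule accepts is accepted.
#'
#' @param ruleset an [sqi_ruleset()].
#' @param sqi_row named list / one-row data frame of SQI values (NA allowed;
#'   every ruleset SQI name must be present).
#' @return list with `label` (`"accept"`/`"reject"`) and `triggered_rule`
#'   (name or `NA`).
#' @export
apply_ruleset <- function(ruleset, sqi_row) {
  row <- as.list(sqi_row)
  missing <- setdiff(ruleset$order, names(row))
  if (length(missing)) {
    stop_config("SQI row is missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (nm in ruleset$order) {
    d <- apply_rule(ruleset$rules[[nm]], row[[nm]])
    if (d == "reject") {
      return(list(label = "reject", triggered_rule = nm))
    }
  }
  list(label = "accept", triggered_rule = NA_character_)
}

#' Accept-percentile threshold
#'
#' Sets the threshold at the q-th linear-interpolation percentile of the
#' accept-class values; `side` picks which tail of the accept distribution
#' is to be rejected (upper: values above the threshold reject).
#'
#' @param accept_values numeric vector (>= 20 values).
#' @param q percentile in (0, 100), default 95.
#' @param side `"upper"` or `"lower"`.
#' @return list with `threshold`, `side`, and the reject `op` implied
#'   (`">"` for upper, `"<"` for lower).
#' @export
threshold_percentile <- function(accept_values, q = 95,
                                 side = c("upper", "lower")) {
  side <- match.arg(side)
  v <- accept_values[is.finite(accept_values)]
  if (length(v) < 20L) stop_input("threshold_percentile needs >= 20 values")
  qq <- if (side == "upper") q / 100 else 1 - q / 100
  thr <- stats::quantile(v, qq, type = 7, names = FALSE)
  list(threshold = thr, side = side, op = if (side == "upper") ">" else "<")
}

#' Quantile-grid threshold search
#'
#' Brute-force search over candidate thresholds (quantiles of the pooled
#' values on the grid `step_quantile, 2*step_quantile, ..., 1-step_quantile`)
#' and both rejection directions, maximizing balanced accuracy
#' `(sensitivity + specificity)/2` over the accept/reject classes. Ties are
#' broken toward the smallest threshold, reject-below preferred.
#'
#' @param accept_values,reject_values numeric vectors (>= 20 each).
#' @param step_quantile quantile grid step, default 0.05.
#' @return list with `threshold`, `direction` (`"reject_below"` or
#'   `"reject_above"`), and `balanced_accuracy`.
#' @export
threshold_search <- function(accept_values, reject_values,
                             step_quantile = 0.05) {
  a <- accept_values[is.finite(accept_values)]
  r <- reject_values[is.finite(reject_values)]
  if (length(a) < 20L || length(r) < 20L) {
    stop_input("threshold_search needs >= 20 values per class")
  }
  if (length(unique(c(a, r))) < 2L) stop_input("degenerate classes")
  pooled <- c(a, r)
  grid <- seq(step_quantile, 1 - step_quantile, by = step_quantile)
  cands <- unique(stats::quantile(pooled, grid, type = 7, names = FALSE))
  best <- list(balanced_accuracy = -Inf, threshold = NA_real_, direction = NA)
  for (thr in cands) {
    # reject_below: predict reject when value < thr
    ba_below <- (mean(a >= thr) + mean(r < thr)) / 2
    ba_above <- (mean(a <= thr) + mean(r > thr)) / 2
    if (ba_below > best$balanced_accuracy) {
      best <- list(balanced_accuracy = ba_below, threshold = thr,
                   direction = "reject_below")
    }
    if (ba_above > best$balanced_accuracy) {
      best <- list(balanced_accuracy = ba_above, threshold = thr,
                   direction = "reject_above")
    }
  }
  best
}

# build a one-boundary rule from a threshold_search result
rule_from_search <- function(sqi_name, search) {
  op <- if (search$direction == "reject_below") "<" else ">"
  sqi_rule(sqi_name,
           list(list(op = op, value = search$threshold, decision = "reject")),
           na_decision = "reject")
}

#' Search SQI pairs for the most discriminative AND-ruleset
#'
#' For every unordered pair of candidate SQIs, derives each member's
#' threshold with [threshold_search()], builds the two-rule AND ruleset, and
#' evaluates it on the labelled table: per-class accuracy, overall accuracy,
#' Brier score of the 0/1 decision, area under the ROC of the pair's
#' combined score (the minimum of the two members' accept-oriented quantile
#' scores), and F-beta. Pairs are ranked by ROC AUC.
#'
#' @param sqi_table data frame of SQI values.
#' @param labels character vector (`"accept"`/`"reject"`), one per row.
#' @param candidate_sqis column names to search over (>= 2).
#' @param beta F-beta weight, default 1.
#' @return data frame ranked by `roc_auc`, one row per pair, with an
#'   attribute `rulesets` (named list of the fitted [sqi_ruleset()]s).
#' @export
pair_search <- function(sqi_table, labels, candidate_sqis, beta = 1) {
  if (length(candidate_sqis) < 2L) stop_input("need >= 2 candidate SQIs")
  labels <- as.character(labels)
  if (length(unique(labels[labels %in% c("accept", "reject")])) < 2L) {
    stop_input("labels must contain both accept and reject")
  }
  missing <- setdiff(candidate_sqis, names(sqi_table))
  if (length(missing)) stop_config("table is missing column(s): %s",
                                   paste(missing, collapse = ", "))
  is_acc <- labels == "accept"
  searches <- lapply(candidate_sqis, function(nm) {
    threshold_search(sqi_table[[nm]][is_acc], sqi_table[[nm]][!is_acc])
  })
  names(searches) <- candidate_sqis
  # accept-oriented score in [0,1]: empirical quantile, flipped when the
  # search rejects above
  scores <- lapply(candidate_sqis, function(nm) {
    v <- sqi_table[[nm]]
    s <- (rank(v, ties.method = "average", na.last = "keep") - 0.5) / sum(!is.na(v))
    if (searches[[nm]]$direction == "reject_above") s <- 1 - s
    s[is.na(s)] <- 0
    s
  })
  names(scores) <- candidate_sqis
  pairs <- utils::combn(candidate_sqis, 2L, simplify = FALSE)
  rulesets <- list()
  rows <- lapply(pairs, function(pr) {
    rs <- sqi_ruleset(list(rule_from_search(pr[1L], searches[[pr[1L]]]),
                           rule_from_search(pr[2L], searches[[pr[2L]]])))
    key <- paste(pr, collapse = "+")
    rulesets[[key]] <<- rs
    dec <- vapply(seq_len(nrow(sqi_table)), function(i) {
      apply_ruleset(rs, sqi_table[i, , drop = FALSE])$label
    }, "")
    pred_acc <- dec == "accept"
    acc_accept <- mean(pred_acc[is_acc])
    acc_reject <- mean(!pred_acc[!is_acc])
    overall <- mean(pred_acc == is_acc)
    brier <- mean((as.numeric(pred_acc) - as.numeric(is_acc))^2)
    comb <- pmin(scores[[pr[1L]]], scores[[pr[2L]]])
    auc <- as.numeric(pROC::auc(pROC::roc(response = factor(is_acc,
                                                            levels = c(FALSE, TRUE)),
                                          predictor = comb, quiet = TRUE,
                                          direction = "<")))
    tp <- sum(pred_acc & is_acc)
    fp <- sum(pred_acc & !is_acc)
    fn <- sum(!pred_acc & is_acc)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    fbeta <- if (prec + rec > 0) {
      (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
    } else 0
    data.frame(sqi_pair = key, accept_accuracy = acc_accept,
               reject_accuracy = acc_reject, accuracy = overall,
               brier = brier, roc_auc = auc, fbeta = fbeta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$roc_auc, out$sqi_pair), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rulesets") <- rulesets
  out
}
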