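as_adj_input <- function(x) {
  if (igraph::is_igraph(x)) return(adjacency_matrix(x))
  if (inherits(x, "ccs_fit")) return(x$adjacency)
  as.matrix(x)
}

upper_pairs <- function(a) a[upper.tri(a)]

# average precision of the ranked positive class (step-wise PR curve,
# ties grouped at equal scores)
average_precision <- function(labels, scores) {
  if (!any(labels == 1)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  grp <- cumsum(!duplicated(sc))
  tp <- unname(tapply(lab, grp, sum))
  np <- unname(tapply(lab, grp, length))
  ctp <- cumsum(tp); cn <- cumsum(np)
  prec <- ctp / cn
  rec <- ctp / sum(lab)
  sum(diff(c(0, rec)) * prec)
}

auroc_score <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Score a reconstructed adjacency against the truth
#'
#' Confusion counts are taken over the unordered non-diagonal node pairs.
#' The success rate is the product of the link recovery rate
#' `SREL = TP / (TP + FN)` and the non-link recovery rate
#' `SRNC = TN / (FP + TN)`. Ranking metrics (AUROC and the area under the
#' precision-recall curve) use the fractional pre-threshold scores when
#' supplied, and the binary estimate otherwise (a degenerate two-point
#' curve).
#'
#' @param estimate Binary adjacency matrix, [igraph::igraph] or `ccs_fit`.
#' @param truth True adjacency matrix or [igraph::igraph].
#' @param scores Optional symmetric matrix of fractional link scores.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `srel`, `srnc`, `sr`,
#'   `auroc`, `aupr`. With no true links, `srel` and `sr` are `NA`.
#' @examples
#' g <- generate_network("random", 20, 4, seed = 1)
#' a <- adjacency_matrix(g)
#' score_reconstruction(a, g)   # perfect: sr = 1
#' @export
score_reconstruction <- function(estimate, truth, scores = NULL) {
  if (inherits(estimate, "ccs_fit") && is.null(scores))
    scores <- estimate$scores
  est <- as_adj_input(estimate)
  tru <- as_adj_input(truth)
  if (!all(dim(est) == dim(tru))) stop("estimate and truth sizes differ")
  e <- upper_pairs(est) > 0.5
  t_ <- upper_pairs(tru) > 0.5
  tp <- sum(e & t_); fp <- sum(e & !t_)
  tn <- sum(!e & !t_); fn <- sum(!e & t_)
  srel <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  srnc <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  sc <- if (is.null(scores)) as.numeric(e) else upper_pairs(as.matrix(scores))
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 srel = srel, srnc = srnc, sr = srel * srnc,
                 auroc = auroc_score(as.numeric(t_), sc),
                 aupr = average_precision(as.numeric(t_), sc))
}

#' Per-node success rates
#'
#' Applies the success-rate decomposition to each node's row of candidates
#' (its `N - 1` potential neighbours). Nodes with no true neighbours have
#' `srel = 1` by convention; an all-`NA` estimate row (solver failure)
#' scores 0.
#'
#' @param estimate,truth Adjacency matrices (or igraph / `ccs_fit`).
#' @return Tibble with `node`, `srel`, `srnc`, `sr`.
#' @export
per_node_success <- function(estimate, truth) {
  est <- as_adj_input(estimate)
  tru <- as_adj_input(truth)
  n <- nrow(tru)
  out <- lapply(seq_len(n), function(i) {
    e <- est[i, -i]; t_ <- tru[i, -i] > 0.5
    if (anyNA(e)) return(tibble::tibble(node = i, srel = 0, srnc = 0,
                                        sr = 0))
    e <- e > 0.5
    tp <- sum(e & t_); fn <- sum(!e & t_)
    fp <- sum(e & !t_); tn <- sum(!e & !t_)
    srel <- if (tp + fn > 0) tp / (tp + fn) else 1
    srnc <- if (fp + tn > 0) tn / (fp + tn) else 1
    tibble::tibble(node = i, srel = srel, srnc = srnc, sr = srel * srnc)
  })
  dplyr::bind_rows(out)
}

#' Node-level completely-correct frequencies and the minimum failing degree
#'
#' Given repeated reconstruction experiments, `fr(i)` is the fraction of
#' runs in which node `i`'s whole neighbourhood was recovered exactly. The
#' minimum failing degree is the smallest degree among nodes with
#' `fr < 1` (`Inf` when every node is perfect in every run): nodes below
#' it are always reconstructed correctly.
#'
#' @param success Logical matrix, runs in rows and nodes in columns:
#'   `TRUE` when the node was completely correct in that run.
#' @param degrees Integer vector of true node degrees.
#' @return A `node_frequency_report`: list with tibble `freq`
#'   (`node`, `degree`, `fr`) and scalar `md`.
#' @export
node_frequencies <- function(success, degrees) {
  success <- as.matrix(success)
  if (nrow(success) < 1) stop("at least one run is required")
  if (ncol(success) != length(degrees))
    stop("degrees must have one entry per node")
  fr <- colMeans(success)
  md <- if (any(fr < 1)) min(degrees[fr < 1]) else Inf
  structure(list(freq = tibble::tibble(node = seq_along(fr),
                                       degree = as.numeric(degrees),
                                       fr = fr),
                 md = md, n_runs = nrow(success)),
            class = "node_frequency_report")
}

#' @export
print.node_frequency_report <- function(x, ...) {
  cat("Completely-correct frequencies over ", x$n_runs, " runs; ",
      sum(x$freq$fr < 1), " imperfect node(s); minimum failing degree ",
      x$md, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.node_frequency_report <- function(x, ...) x$freq

#' Regress reconstruction success on payoff-diversity diagnostics
#'
#' Ordinary least squares of the success rate on the number of distinct
#' payoff values (`ndp`) and the modal element frequency (`mf`) across
#' strategy compositions, with standardized coefficients
#' (`slope * sd(predictor) / sd(response)`, sample variance convention)
#' and the Pearson correlations of the response with each predictor.
#'
#' @param groups Data frame with numeric columns `sr`, `ndp`, `mf`
#'   (at least 3 rows), e.g. [diversity_benchmark()].
#' @return A `diversity_fit`; see [tidy()] and [glance()] methods.
#' @examples
#' fit <- diversity_analysis(diversity_benchmark())
#' glance(fit)$r.squared      # ~ 0.933
#' @export
diversity_analysis <- function(groups) {
  stopifnot(all(c("sr", "ndp", "mf") %in% names(groups)))
  if (nrow(groups) < 3) stop("at least 3 groups are required")
  fit <- lm(sr ~ ndp + mf, data = groups)
  if (anyNA(coef(fit)))
    warning("rank-deficient fit: predictors are collinear")
  cf <- coef(fit)
  std <- c(NA_real_,
           cf["ndp"] * sd(groups$ndp) / sd(groups$sr),
           cf["mf"] * sd(groups$mf) / sd(groups$sr))
  structure(list(fit = fit,
                 coefficients = cf,
                 std_coefficients = unname(std),
                 r_squared = summary(fit)$r.squared,
                 pearson_sr_ndp = cor(groups$sr, groups$ndp),
                 pearson_sr_mf = cor(groups$sr, groups$mf),
                 data = tibble::as_tibble(groups)),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Diversity regression: sr ~ ndp + mf over ", nrow(x$data),
      " groups (R^2 = ", round(x$r_squared, 3), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn diversity_analysis Coefficient-level summary: term,
#'   estimate, standardized estimate, t statistic, p value.
#' @param x A `diversity_fit`.
#' @param ... Unused.
#' @export
tidy.diversity_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = unname(sm[, 1]),
                 std_estimate = unname(x$std_coefficients),
                 statistic = unname(sm[, 3]),
                 p.value = unname(sm[, 4]))
}

#' @describeIn diversity_analysis One-row model summary with fit quality
#'   and the response-predictor correlations.
#' @export
glance.diversity_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 pearson_sr_ndp = x$pearson_sr_ndp,
                 pearson_sr_mf = x$pearson_sr_mf,
                 nobs = nrow(x$data))
}
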