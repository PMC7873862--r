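#' Confusion-matrix statistics for binary growth/essentiality calls
#'
#' @param pred,obs logical vectors of equal length (>= 1).
#' @return a `confusion_stats`: list with `tp`, `tn`, `fp`, `fn`, `n`,
#'   `accuracy` (percent), `mcc` (Matthews correlation coefficient,
#'   defined as 0 when any marginal is 0).
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop(sprintf("length mismatch: %d predictions vs %d observations",
                 length(pred), length(obs)))
  }
  if (length(pred) == 0L) stop("need at least one prediction")
  pred <- as.logical(pred); obs <- as.logical(obs)
  tp <- sum(pred & obs); tn <- sum(!pred & !obs)
  fp <- sum(pred & !obs); fn <- sum(!pred & obs)
  n <- tp + tn + fp + fn
  acc <- 100 * (tp + tn) / n
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 accuracy = acc, mcc = mcc), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> n=%d TP=%d TN=%d FP=%d FN=%d | accuracy %.1f%% | MCC %.3f\n",
              x$n, x$tp, x$tn, x$fp, x$fn, x$accuracy, x$mcc))
  invisible(x)
}

#' Binarize phenotype-array absorbances into growth calls
#'
#' Wells with a pre-recorded `observed_growth` keep it.  Otherwise the
#' dye signal `a590 - a750` is thresholded; the default threshold is the
#' 25th percentile of the negative-control wells plus three standard
#' deviations of those wells (a plate-level noise floor).
#'
#' @param wells data.frame with columns `substrate`, `a590`, `a750` and
#'   optionally `observed_growth`.
#' @param threshold explicit signal threshold; overrides the control-based
#'   default.
#' @param negative_controls substrate labels treated as negative controls.
#' @return the data.frame with a filled `observed_growth` column.
#' @export
binarize_phenotypes <- function(wells, threshold = NULL,
                                negative_controls = c("negative control",
                                                      "water")) {
  sig <- wells$a590 - wells$a750
  if (is.null(wells$observed_growth)) wells$observed_growth <- NA
  todo <- is.na(wells$observed_growth)
  if (!any(todo)) return(wells)
  if (is.null(threshold)) {
    ctrl <- sig[tolower(wells$substrate) %in% tolower(negative_controls)]
    if (length(ctrl) == 0L) {
      stop("no negative-control wells and no explicit threshold")
    }
    threshold <- stats::quantile(ctrl, 0.25) + 3 * stats::sd(ctrl)
    if (is.na(threshold)) threshold <- stats::quantile(ctrl, 0.25)
  }
  wells$observed_growth[todo] <- sig[todo] >= threshold
  wells
}

#' Simulate growth phenotypes for a substrate array
#'
#' For each simulable well, the exchange reaction supplying the well's
#' element class (C/N/P/S) in the base medium is closed and exchanges for
#' the mapped metabolite(s) are opened at the same uptake rate; growth is
#' then called by FBA.  Substrates mapping to several metabolite ids
#' (anomeric forms) open all of them.  Mapped metabolites without an
#' exchange reaction get one auto-created (and logged).  Wells whose
#' substrate is absent from the map, or maps to no model metabolite, are
#' counted but excluded from simulation.
#'
#' @param model a `metabolic_model` with an objective.
#' @param wells data.frame with columns `substrate`, `element_class`, and
#'   optionally `observed_growth` (or `a590`/`a750`, see
#'   [binarize_phenotypes()]).
#' @param substrate_map data.frame with columns `substrate`,
#'   `metabolite_id` (several rows per substrate allowed; `NA` marks a
#'   known-unmappable substrate).
#' @param base_medium named numeric medium (see [apply_medium()]).
#' @param element_sources named character vector: element class ->
#'   exchange reaction replaced for that class.
#' @param growth_threshold objective flux above which growth is called.
#' @return list with `wells` (input plus `simulable`, `predicted_growth`),
#'   `coverage` (counts), and `created_exchanges`.
#' @export
simulate_phenotypes <- function(model, wells, substrate_map, base_medium,
                                element_sources = c(C = "EX_glc__D_e",
                                                    N = "EX_nh4_e",
                                                    P = "EX_pi_e"),
                                growth_threshold = 1e-6) {
  if (!is.null(wells$a590) && is.null(wells$observed_growth)) {
    wells <- binarize_phenotypes(wells)
  }
  created <- character(0)
  wells$simulable <- FALSE
  wells$predicted_growth <- NA
  uptake <- min(base_medium)   # most permissive uptake in the base medium
  default_uptake <- -10
  for (i in seq_len(nrow(wells))) {
    sub <- wells$substrate[i]
    cls <- wells$element_class[i]
    mets <- substrate_map$metabolite_id[substrate_map$substrate == sub]
    mets <- mets[!is.na(mets)]
    mets <- mets[mets %in% model$metabolites$id]
    if (length(mets) == 0L) next
    if (!cls %in% names(element_sources)) next
    wells$simulable[i] <- TRUE
    m2 <- model
    exs <- character(0)
    for (met in mets) {
      ex_id <- paste0("EX_", met)
      if (!ex_id %in% names(m2$reactions)) {
        m2 <- add_reaction(m2, ex_id, stats::setNames(-1, met),
                           lower_bound = 0, upper_bound = 1000,
                           kind = "exchange")
        created <- union(created, ex_id)
      }
      exs <- c(exs, ex_id)
    }
    med <- base_medium[names(base_medium) != element_sources[[cls]]]
    swap_uptake <- if (element_sources[[cls]] %in% names(base_medium)) {
      base_medium[[element_sources[[cls]]]]
    } else default_uptake
    med <- c(med, stats::setNames(rep(swap_uptake, length(exs)), exs))
    res <- fba(m2, med)
    wells$predicted_growth[i] <- res$status == "optimal" &&
      res$objective > growth_threshold
  }
  list(wells = wells,
       coverage = c(total = nrow(wells), simulable = sum(wells$simulable),
                    excluded = sum(!wells$simulable)),
       created_exchanges = created, uptake_reference = uptake)
}

#' Score phenotype predictions against observed growth
#'
#' @param sim result of [simulate_phenotypes()].
#' @return a `confusion_stats` over the simulable wells.
#' @export
phenotype_concordance <- function(sim) {
  w <- sim$wells[sim$wells$simulable, , drop = FALSE]
  confusion(w$predicted_growth, w$observed_growth)
}

#' Concordance of predicted and observed gene essentiality
#'
#' For every (gene, condition) pair, the predicted call comes from
#' GPR-masked single-gene deletion FBA and the observed call from the
#' fitness table rule: essential iff flagged globally essential or the
#' fitness score is below `cutoff`.  Reports per-condition and pooled
#' confusion statistics, and partitions genes by their OBSERVED calls
#' into always / never / conditionally essential, with accuracy reported
#' separately on the conditional subset.
#'
#' @param model a `metabolic_model` with an objective.
#' @param fitness data.frame with columns `gene`, `condition`, `score`,
#'   and optionally `global_essential`.
#' @param media named list of media covering every condition in
#'   `fitness`.
#' @param exclude genes to drop (e.g. mitochondrially encoded genes with
#'   no insertion data).
#' @param cutoff fitness-score cutoff (log2 scale) below which a gene is
#'   observed essential.
#' @param essentiality_threshold growth-ratio cutoff for the predicted
#'   call.
#' @param predictions optional precomputed [model_deletion_calls()]
#'   output.
#' @return list with `pooled` (`confusion_stats`), `per_condition`
#'   (named list), `partition` (data.frame `gene`, `class`),
#'   `conditional` (`confusion_stats` on conditionally essential genes,
#'   `NULL` if none), `n_genes`, `cutoff`, `essentiality_threshold`,
#'   and `pairs` (the per-pair calls).
#' @export
essentiality_concordance <- function(model, fitness, media,
                                     exclude = character(0), cutoff = -2,
                                     essentiality_threshold = 0.1,
                                     predictions = NULL) {
  conds <- unique(fitness$condition)
  missing_media <- setdiff(conds, names(media))
  if (length(missing_media) > 0L) {
    stop("condition(s) without a medium: ",
         paste(missing_media, collapse = ", "))
  }
  genes <- setdiff(intersect(unique(fitness$gene), model$genes), exclude)
  if (length(genes) == 0L) stop("no genes shared by model and fitness table")
  if (is.null(predictions)) {
    predictions <- model_deletion_calls(
      model, media[conds], genes,
      essentiality_threshold = essentiality_threshold)
  }
  if (is.null(fitness$global_essential)) fitness$global_essential <- FALSE
  fit <- fitness[fitness$gene %in% genes, , drop = FALSE]
  fit$observed <- fit$global_essential | fit$score < cutoff
  key <- function(g, cond) paste(g, cond, sep = "\r")
  pred_lookup <- stats::setNames(predictions$essential,
                                 key(predictions$gene, predictions$condition))
  fit$predicted <- pred_lookup[key(fit$gene, fit$condition)]
  fit <- fit[!is.na(fit$predicted), , drop = FALSE]
  pooled <- confusion(fit$predicted, fit$observed)
  per_condition <- lapply(split(fit, fit$condition), function(d) {
    confusion(d$predicted, d$observed)
  })
  obs_by_gene <- tapply(fit$observed, fit$gene, function(v) {
    if (all(v)) "always" else if (!any(v)) "never" else "conditional"
  })
  partition <- data.frame(gene = names(obs_by_gene),
                          class = as.character(obs_by_gene),
                          stringsAsFactors = FALSE)
  cond_genes <- partition$gene[partition$class == "conditional"]
  conditional <- if (length(cond_genes) > 0L) {
    d <- fit[fit$gene %in% cond_genes, , drop = FALSE]
    confusion(d$predicted, d$observed)
  } else NULL
  list(pooled = pooled, per_condition = per_condition,
       partition = partition, conditional = conditional,
       n_genes = length(unique(fit$gene)), cutoff = cutoff,
       essentiality_threshold = essentiality_threshold,
       pairs = fit[, c("gene", "condition", "predicted", "observed")])
}

#' Partition sizes of an essentiality concordance
#' @param conc result of [essentiality_concordance()].
#' @return named integer vector (always, never, conditional).
#' @export
partition_sizes <- function(conc) {
  cls <- factor(conc$partition$class,
                levels = c("always", "never", "conditional"))
  stats::setNames(as.integer(table(cls)), levels(cls))
}
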