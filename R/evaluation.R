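# Performance evaluation: regression metrics, highly-decreasing-mutation
# classification metrics (ROC / precision-recall / max-MCC), the three
# cross-validation protocols and dataset curation.

#' Regression agreement metrics
#'
#' Pearson R, RMSE = sqrt(mean squared prediction error) and the slope of
#' the least-squares line of experimental on predicted values.
#'
#' @param pred,exp numeric vectors of equal length (n >= 3)
#' @return list(r, rmse, slope)
#' @export
regression_metrics <- function(pred, exp) {
  stopifnot(length(pred) == length(exp), length(pred) >= 3)
  if (stats::sd(pred) == 0 || stats::sd(exp) == 0)
    stop("zero variance: correlation undefined")
  list(r = stats::cor(pred, exp),
       rmse = sqrt(mean((pred - exp)^2)),
       slope = unname(stats::coef(stats::lm(exp ~ pred))[2]))
}

#' @noRd
.mcc <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Classification metrics for highly decreasing mutations
#'
#' Labels are `exp >= threshold` (default 1 kcal/mol).  The ROC curve is a
#' threshold sweep over the predictions with trapezoidal AUC; the
#' precision-recall AUC uses step interpolation; MCC is maximized over all
#' distinct prediction thresholds (0 when a confusion-matrix factor is 0).
#'
#' @param pred predicted ddG values
#' @param exp experimental ddG values
#' @param threshold positive-class cutoff on `exp`, kcal/mol
#' @return list(auc_roc, auc_pr, max_mcc, n_pos, n_neg)
#' @export
classification_metrics <- function(pred, exp, threshold = 1.0) {
  stopifnot(length(pred) == length(exp))
  lab <- exp >= threshold
  if (all(lab) || !any(lab))
    stop("both classes must be present (threshold ", threshold, ")")
  np <- sum(lab); nn <- sum(!lab)
  ths <- c(Inf, sort(unique(pred), decreasing = TRUE))
  tpr <- fpr <- prec <- mcc <- numeric(length(ths))
  for (k in seq_along(ths)) {
    pp <- pred >= ths[k]
    tp <- sum(pp & lab); fp <- sum(pp & !lab)
    fn <- np - tp; tn <- nn - fp
    tpr[k] <- tp / np
    fpr[k] <- fp / nn
    prec[k] <- if (tp + fp == 0) 1 else tp / (tp + fp)
    mcc[k] <- .mcc(tp, tn, fp, fn)
  }
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  auc_pr <- sum(diff(tpr) * utils::tail(prec, -1))
  list(auc_roc = auc_roc, auc_pr = auc_pr, max_mcc = max(mcc),
       n_pos = np, n_neg = nn)
}

#' Full evaluation report for a prediction set
#'
#' @param pred,exp numeric vectors
#' @param threshold highly-decreasing cutoff for the classification part
#' @return list combining [regression_metrics()] and
#'   [classification_metrics()] plus n
#' @export
evaluation_report <- function(pred, exp, threshold = 1.0) {
  rm_ <- regression_metrics(pred, exp)
  cm <- tryCatch(classification_metrics(pred, exp, threshold),
                 error = function(e) list(auc_roc = NA_real_,
                                          auc_pr = NA_real_,
                                          max_mcc = NA_real_))
  c(rm_, cm[c("auc_roc", "auc_pr", "max_mcc")], list(n = length(pred)))
}

#' Cross-validation of the scoring function
#'
#' CV1: repeated random 50/50 mutation splits; CV2: repeated 80/20 splits;
#' CV3: leave-one-complex-out (folds never share a complex).  CV1/CV2
#' aggregate as the mean per-round R and RMSE; CV3 aggregates as metrics on
#' the pooled out-of-fold predictions.
#'
#' @param data data.frame with the 11 features, `ddg_exp` and `complex_id`
#' @param scheme "CV1", "CV2" or "CV3"
#' @param repeats number of rounds for CV1/CV2
#' @param seed RNG seed for the random splits
#' @param threshold highly-decreasing cutoff used in pooled metrics
#' @return list with `scheme`, `rounds` (per-round data.frame),
#'   `aggregate` (named list), and for CV3 `pooled` (data.frame of
#'   out-of-fold predictions)
#' @export
cross_validate <- function(data, scheme = c("CV3", "CV1", "CV2"),
                           repeats = 100, seed = 1, threshold = 1.0) {
  scheme <- match.arg(scheme)
  if (!"complex_id" %in% names(data)) stop("data needs a complex_id column")
  n <- nrow(data)
  if (scheme %in% c("CV1", "CV2")) {
    frac <- if (scheme == "CV1") 0.5 else 0.8
    rounds <- .with_seed(seed, {
      out <- vector("list", repeats)
      for (k in seq_len(repeats)) {
        tr <- sample(n, round(frac * n))
        te <- setdiff(seq_len(n), tr)
        model <- fit_ddg_model(data[tr, ])
        pred <- predict(model, data[te, ])
        m <- regression_metrics(pred, data$ddg_exp[te])
        out[[k]] <- data.frame(round = k, r = m$r, rmse = m$rmse,
                               slope = m$slope, n_test = length(te))
      }
      do.call(rbind, out)
    })
    list(scheme = scheme, rounds = rounds,
         aggregate = list(r = mean(rounds$r), rmse = mean(rounds$rmse),
                          slope = mean(rounds$slope), n = n))
  } else {
    complexes <- unique(data$complex_id)
    if (length(complexes) < 2)
      stop("CV3 needs at least two complexes")
    pooled <- list()
    rounds <- list()
    for (cid in complexes) {
      te <- which(data$complex_id == cid)
      tr <- setdiff(seq_len(n), te)
      if (length(tr) <= 12)
        stop("degenerate fold: complex ", cid,
             " holds nearly all mutations")
      model <- fit_ddg_model(data[tr, ])
      pred <- predict(model, data[te, , drop = FALSE])
      pooled[[cid]] <- data.frame(complex_id = cid,
                                  mutation = if ("mutation" %in% names(data))
                                    data$mutation[te] else NA,
                                  pred = pred, ddg_exp = data$ddg_exp[te],
                                  stringsAsFactors = FALSE)
      rounds[[cid]] <- data.frame(complex_id = cid, n_test = length(te))
    }
    pooled <- do.call(rbind, c(pooled, make.row.names = FALSE))
    agg <- evaluation_report(pooled$pred, pooled$ddg_exp, threshold)
    list(scheme = scheme, rounds = do.call(rbind, rounds),
         aggregate = agg, pooled = pooled)
  }
}

#' Curate a raw ddG mutation table
#'
#' Applies the training-set construction filters in order: (1) complexes
#' with modified residues/nucleotides at the binding interface, (2) protein
#' shorter than 20 amino acids or RNA shorter than 5 nucleotides, (3)
#' mutations at metal coordination sites, (4) RNA-sequence similarity
#' between the structure and the affinity assay below 80% global-alignment
#' identity (only checked when both sequences are supplied), then (5)
#' averages repeated measurements of the same mutation when their spread is
#' below 1 kcal/mol and rejects them otherwise.
#'
#' Expected columns: pdb_id, chain, position, wt_aa, mut_aa, ddg_exp;
#' optional: protein_length, rna_length, modified_interface (logical),
#' metal_site (logical), rna_seq_structure, rna_seq_assay.
#'
#' @param raw data.frame of raw records
#' @param similarity_min retention threshold on RNA sequence identity
#' @return list(curated = data.frame, rejected = data.frame with a
#'   `reason` column)
#' @export
curate_dataset <- function(raw, similarity_min = 0.8) {
  req <- c("pdb_id", "chain", "position", "wt_aa", "mut_aa", "ddg_exp")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(raw))
  bad_row <- !is.finite(suppressWarnings(as.numeric(raw$ddg_exp)))
  reason[bad_row & is.na(reason)] <- "malformed ddG value"
  if ("modified_interface" %in% names(raw))
    reason[isTRUE_v(raw$modified_interface) & is.na(reason)] <-
      "modified residue/nucleotide at binding interface"
  if ("protein_length" %in% names(raw))
    reason[!is.na(raw$protein_length) & raw$protein_length < 20 &
             is.na(reason)] <- "protein length < 20 amino acids"
  if ("rna_length" %in% names(raw))
    reason[!is.na(raw$rna_length) & raw$rna_length < 5 & is.na(reason)] <-
      "RNA length < 5 nucleotides"
  if ("metal_site" %in% names(raw))
    reason[isTRUE_v(raw$metal_site) & is.na(reason)] <-
      "mutation at metal coordination site"
  if (all(c("rna_seq_structure", "rna_seq_assay") %in% names(raw))) {
    both <- !is.na(raw$rna_seq_structure) & !is.na(raw$rna_seq_assay) &
      nzchar(raw$rna_seq_structure) & nzchar(raw$rna_seq_assay)
    for (i in which(both & is.na(reason))) {
      sim <- rna_identity(raw$rna_seq_structure[i], raw$rna_seq_assay[i])
      if (sim < similarity_min)
        reason[i] <- sprintf("RNA sequence similarity %.0f%% < %.0f%%",
                             100 * sim, 100 * similarity_min)
    }
  }
  kept <- raw[is.na(reason), , drop = FALSE]
  kept$ddg_exp <- as.numeric(kept$ddg_exp)
  rejected <- raw[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  # average multi-measurements when the spread is < 1 kcal/mol
  key <- paste(kept$pdb_id, kept$chain, kept$position, kept$wt_aa,
               kept$mut_aa)
  out <- list()
  rej2 <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1) {
      out[[k]] <- kept[idx, , drop = FALSE]
    } else {
      v <- kept$ddg_exp[idx]
      if (max(v) - min(v) < 1) {
        row <- kept[idx[1], , drop = FALSE]
        row$ddg_exp <- mean(v)
        out[[k]] <- row
      } else {
        bad <- kept[idx, , drop = FALSE]
        bad$reason <- sprintf("inconsistent repeated measurements (spread %.2f kcal/mol)",
                              max(v) - min(v))
        rej2[[k]] <- bad
      }
    }
  }
  curated <- do.call(rbind, c(out, make.row.names = FALSE))
  if (length(rej2) > 0)
    rejected <- rbind(rejected, do.call(rbind, c(rej2,
                                                 make.row.names = FALSE)))
  rownames(curated) <- NULL
  rownames(rejected) <- NULL
  list(curated = curated, rejected = rejected)
}

#' @noRd
isTRUE_v <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' Global-alignment identity between two RNA sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) with identity
#' defined as matches divided by alignment length.
#'
#' @param a,b RNA/DNA sequence strings (T and U treated alike)
#' @return identity fraction in [0, 1]
#' @export
rna_identity <- function(a, b) {
  a <- chartr("Uu", "Tt", a)
  b <- chartr("Uu", "Tt", b)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(a)),
                                      Biostrings::DNAString(toupper(b)),
                                      type = "global")
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Load a ddG mutation table from a TSV file
#'
#' The bundled synthetic training-set stand-in
#' (`system.file("extdata", "s248_synthetic.tsv", package = "priddg")`) has
#' the same layout: one row per mutation with pdb_id, chain, position,
#' wt_aa, mut_aa, ddg_exp and category flags.
#'
#' @param file path to a tab-separated table
#' @return data.frame
#' @export
read_ddg_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
}
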