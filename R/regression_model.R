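# The 11-feature vector, the multiple linear regression scoring function
# and its diagnostics (coefficient p-values, |t| importance, VIF).

FEATURE_NAMES <- c("dd_evdw", "dd_evdw_rep", "dd_eelec", "n_inter",
                   "r_l_sa", "closeness", "delta_sa", "p_coil",
                   "delta_omh", "delta_p_fwy", "delta_p_krde")

#' Compute the 11-feature vector for one mutation
#'
#' Runs the full per-mutation pipeline: completes missing side chains,
#' minimizes the wild-type complex, builds and minimizes the mutant, then
#' evaluates the three energy differences, the interface and surface
#' descriptors, the network closeness of the mutated site and the three
#' sequence features.
#'
#' @param wt a `pri_complex` with partners assigned
#' @param m a `mutation_spec` or mutation string
#' @param settings a `minimization_settings`
#' @param params an `ff_params`
#' @param wt_min optional pre-minimized wild-type complex (cache for
#'   multiple mutations in the same complex)
#' @param wt_cache optional environment reused across calls to hold
#'   wild-type-only quantities
#' @return named numeric vector of the 11 features, with attributes
#'   `interface` (logical) and `site` (residue uid)
#' @export
featurize <- function(wt, m, settings = minimization_settings(),
                      params = ff_params(), wt_min = NULL,
                      wt_cache = NULL) {
  if (is.character(m)) m <- parse_mutation(m)
  site <- .mutation_uid(m)
  wt <- complete_residues(wt)
  if (is.null(wt_min)) {
    if (!is.null(wt_cache) && !is.null(wt_cache$wt_min)) {
      wt_min <- wt_cache$wt_min
    } else {
      wt_min <- minimize_complex(wt, settings, params)
      if (!is.null(wt_cache)) wt_cache$wt_min <- wt_min
    }
  }
  mut <- build_mutant(wt, m)
  mut_min <- minimize_complex(mut, settings, params)

  if (!is.null(wt_cache) && !is.null(wt_cache$wt_only)) {
    wt_only <- wt_cache$wt_only
  } else {
    ifr <- interface_residues(wt_min)
    rt <- residue_table(wt_min)
    wt_only <- list(
      interface = ifr,
      n_inter = sum(rt$kind[match(ifr, rt$uid)] == "amino-acid"),
      r_l_sa = ratio_length_sasa(wt_min),
      network = build_network(extract_partner(wt_min, 1)),
      sasa_cx = compute_sasa(wt_min),
      ss = assign_secondary_structure(wt_min))
    if (!is.null(wt_cache)) wt_cache$wt_only <- wt_only
  }
  seq_wt <- chain_sequence(wt, m$chain)
  rt_wt <- residue_table(wt)
  pos_in_chain <- which(rt_wt$uid[rt_wt$chain == m$chain] == site)
  if (length(pos_in_chain) == 0) stop("site ", site, " not in chain ",
                                      m$chain)
  comp <- composition_deltas(seq_wt, pos_in_chain, m$wt_aa, m$mut_aa)
  f <- c(
    dd_evdw = dd_evdw(wt_min, mut_min, params),
    dd_evdw_rep = dd_evdw_rep(wt_min, mut_min, site, params),
    dd_eelec = dd_eelec(wt_min, mut_min, site, params),
    n_inter = wt_only$n_inter,
    r_l_sa = wt_only$r_l_sa,
    closeness = unname(closeness_centrality(wt_only$network, site)),
    delta_sa = delta_sa(wt_min, mut_min, site),
    p_coil = p_coil(wt_min, m$chain, sasa = wt_only$sasa_cx,
                    ss = wt_only$ss),
    delta_omh = delta_omh(m$wt_aa, m$mut_aa),
    delta_p_fwy = unname(comp["delta_p_fwy"]),
    delta_p_krde = unname(comp["delta_p_krde"]))
  if (anyNA(f) || any(!is.finite(f)))
    stop("non-finite feature(s) for mutation ", format(m), ": ",
         paste(FEATURE_NAMES[!is.finite(f)], collapse = ", "))
  attr(f, "interface") <- site %in% wt_only$interface
  attr(f, "site") <- site
  f
}

#' Fit the multiple linear regression scoring function
#'
#' Ordinary least squares of experimental ddG on the 11 features in
#' natural units (no standardization), with per-coefficient t-test
#' p-values, |t| importance and variance inflation factors.
#'
#' @param data data.frame containing the 11 feature columns and `ddg_exp`
#' @return object of class `ddg_model`
#' @export
fit_ddg_model <- function(data) {
  miss <- setdiff(c(FEATURE_NAMES, "ddg_exp"), names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) <= 12)
    stop("need more than 12 observations to fit 11 coefficients")
  X <- as.matrix(data[, FEATURE_NAMES])
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite feature values")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    al <- stats::alias(stats::lm(ddg_exp ~ ., data = data[, c(FEATURE_NAMES,
                                                              "ddg_exp")]))
    cols <- rownames(al$Complete)
    stop("rank-deficient design; collinear column(s): ",
         paste(cols, collapse = ", "))
  }
  fit <- stats::lm(ddg_exp ~ ., data = data[, c(FEATURE_NAMES, "ddg_exp")])
  sm <- summary(fit)
  co <- sm$coefficients
  vif <- car::vif(fit)
  structure(list(
    intercept = unname(co[1, 1]),
    coefficients = stats::setNames(co[-1, 1], FEATURE_NAMES),
    p_values = stats::setNames(co[-1, 4], FEATURE_NAMES),
    importance = stats::setNames(abs(co[-1, 3]), FEATURE_NAMES),
    vif = stats::setNames(as.numeric(vif), FEATURE_NAMES),
    sigma = sm$sigma,
    n = nrow(data),
    fingerprint = sprintf("n%d_sum%.6g", nrow(data), sum(data$ddg_exp)),
    lm = fit), class = "ddg_model")
}

#' Predict ddG for one or more feature vectors
#'
#' @param object a `ddg_model`
#' @param features named numeric vector of the 11 features, or a
#'   data.frame/matrix with those columns
#' @param ... unused
#' @return predicted ddG (kcal/mol); positive = binding-affinity-decreasing
#' @export
predict.ddg_model <- function(object, features, ...) {
  if (is.null(dim(features))) {
    if (is.null(names(features)))
      stop("feature vector must be named")
    miss <- setdiff(FEATURE_NAMES, names(features))
    if (length(miss) > 0)
      stop("feature name mismatch; missing: ", paste(miss, collapse = ", "))
    return(unname(object$intercept +
                    sum(object$coefficients * features[FEATURE_NAMES])))
  }
  miss <- setdiff(FEATURE_NAMES, colnames(features))
  if (length(miss) > 0)
    stop("feature name mismatch; missing: ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  unname(object$intercept + as.numeric(X %*% object$coefficients))
}

#' @export
print.ddg_model <- function(x, ...) {
  cat("ddg_model: intercept", signif(x$intercept, 4), "+ 11 features,",
      "fitted on n =", x$n, "\n")
  tab <- data.frame(coef = signif(x$coefficients, 4),
                    p = signif(x$p_values, 3),
                    vif = round(x$vif, 2))
  print(tab)
  invisible(x)
}

#' Write / read a fitted model as a plain-text JSON file
#'
#' @param model a `ddg_model`
#' @param file path
#' @return `file` (write) or a `ddg_model` (read)
#' @export
write_ddg_model <- function(model, file) {
  out <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              p_values = as.list(model$p_values),
              vif = as.list(model$vif),
              sigma = model$sigma, n = model$n,
              fingerprint = model$fingerprint)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file)
  invisible(file)
}

#' @rdname write_ddg_model
#' @export
read_ddg_model <- function(file) {
  x <- jsonlite::fromJSON(file)
  structure(list(
    intercept = x$intercept,
    coefficients = unlist(x$coefficients)[FEATURE_NAMES],
    p_values = unlist(x$p_values)[FEATURE_NAMES],
    vif = unlist(x$vif)[FEATURE_NAMES],
    sigma = x$sigma, n = x$n, fingerprint = x$fingerprint,
    lm = NULL), class = "ddg_model")
}
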