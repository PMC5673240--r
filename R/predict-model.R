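# Sparse multivariate models predicting an ephys property from gene
# expression: two-stage elastic net, leave-one-out evaluation, shuffled
# label null, stratified bootstrap, and transfer to an independently
# normalized dataset.

standardize_columns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1   # constant genes stay constant (coef 0)
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

enet_foldid <- function(n, cfg, stream) {
  if (identical(cfg$inner_nfolds, "loo") || cfg$inner_nfolds >= n) {
    seq_len(n)
  } else {
    with_substream(cfg$seed, stream, sample(rep_len(seq_len(cfg$inner_nfolds), n)))
  }
}

#' Fit a two-stage sparse elastic-net model for one ephys property
#'
#' Stage 1 fits an elastic net (mixing weight `cfg$enet_alpha` over a
#' `cfg$enet_nlambda`-value penalty path) on per-gene z-scored expression
#' against the standardized, registry-transformed property, with the
#' penalty chosen by internal cross-validation minimizing prediction
#' error; the genes with nonzero stage-1 coefficients are selected.
#' Stage 2 refits the same penalized procedure restricted to the selected
#' genes (a penalized refit, since more genes than cell types may be
#' selected). If stage 1 selects nothing, the model is intercept-only.
#'
#' @param X Cell-type x gene numeric matrix (raw modeling-scale
#'   expression; z-scoring is internal and its statistics are stored).
#' @param y Property values, one per cell type, in native units.
#' @param cfg A [run_config()].
#' @param property Registered code; supplies the log10 transform. `NULL`
#'   means y is already on its modeling scale.
#' @return An object of class `sparse_ephys_model`: `gene_scaling`
#'   (per-gene mean/sd), `y_center`/`y_scale`, `selected_genes`,
#'   `coefficients` (standardized scale), `intercept`, `transform`, and
#'   `fit_meta`.
#' @export
fit_two_stage <- function(X, y, cfg = run_config(), property = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y), !anyNA(X))
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (nrow(X) < 8) {
    stop("Need at least 8 cell types with observed values.", call. = FALSE)
  }
  transform <- "identity"
  if (!is.null(property)) {
    y <- to_model_scale(y, property)
    transform <- if (is_log10_property(property)) "log10" else "identity"
  }
  sc <- standardize_columns(X)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  base <- list(
    property = property %||% NA_character_, transform = transform,
    gene_scaling = tibble::tibble(gene = colnames(X), mean = sc$center,
                                  sd = sc$scale),
    y_center = y_center, y_scale = y_scale
  )
  if (y_scale == 0) {
    warning("Constant response; returning an intercept-only model.",
            call. = FALSE)
    return(structure(
      c(base, list(y_scale = 1, selected_genes = character(0),
                   coefficients = numeric(0), intercept = 0,
                   fit_meta = list(note = "constant response"))),
      class = "sparse_ephys_model"
    ))
  }
  yz <- (y - y_center) / y_scale
  foldid <- enet_foldid(length(yz), cfg, "enet_stage1")
  cv1 <- glmnet::cv.glmnet(sc$X, yz, alpha = cfg$enet_alpha,
                           nlambda = cfg$enet_nlambda, foldid = foldid,
                           grouped = FALSE, standardize = FALSE)
  b1 <- stats::coef(cv1, s = "lambda.min")[-1]
  selected <- colnames(X)[b1 != 0]

  if (length(selected) == 0) {
    coefficients <- numeric(0); intercept <- 0
    lambda2 <- NA_real_
  } else if (length(selected) == 1) {
    # glmnet needs >= 2 columns; a single selected gene gets an ordinary
    # least-squares refit
    fit <- stats::lm(yz ~ sc$X[, selected])
    coefficients <- stats::setNames(stats::coef(fit)[2], selected)
    intercept <- stats::coef(fit)[1]
    lambda2 <- 0
  } else {
    cv2 <- glmnet::cv.glmnet(sc$X[, selected, drop = FALSE], yz,
                             alpha = cfg$enet_alpha,
                             nlambda = cfg$enet_nlambda,
                             foldid = foldid, grouped = FALSE,
                             standardize = FALSE)
    b2 <- stats::coef(cv2, s = "lambda.min")
    coefficients <- stats::setNames(as.numeric(b2)[-1], selected)
    intercept <- as.numeric(b2)[1]
    lambda2 <- cv2$lambda.min
  }
  structure(
    c(base, list(
      selected_genes = selected,
      coefficients = coefficients,
      intercept = unname(intercept),
      fit_meta = list(enet_alpha = cfg$enet_alpha,
                      lambda_stage1 = cv1$lambda.min,
                      lambda_stage2 = lambda2,
                      n_selected_stage1 = length(selected),
                      seed = cfg$seed)
    )),
    class = "sparse_ephys_model"
  )
}

#' @export
print.sparse_ephys_model <- function(x, ...) {
  cat(sprintf("<sparse_ephys_model> %s [%s scale]: %d gene(s) selected\n",
              x$property, x$transform, length(x$selected_genes)))
  invisible(x)
}

#' Predict from a sparse ephys model
#'
#' @param object A [fit_two_stage()] model.
#' @param newdata Cell-type x gene matrix containing every training gene,
#'   on the same raw scale as the training matrix (z-scoring uses the
#'   stored training statistics).
#' @param scale `"model"` (registry/modeling scale, default), `"z"`
#'   (standardized response scale) or `"native"` (back-transformed units).
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.sparse_ephys_model <- function(object, newdata,
                                       scale = c("model", "z", "native"), ...) {
  scale <- match.arg(scale)
  miss <- setdiff(object$gene_scaling$gene, colnames(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks training gene(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5),
         call. = FALSE)
  }
  zpred <- rep(object$intercept, nrow(newdata))
  if (length(object$selected_genes) > 0) {
    gs <- object$gene_scaling
    idx <- match(object$selected_genes, gs$gene)
    Xz <- sweep(sweep(newdata[, object$selected_genes, drop = FALSE], 2,
                      gs$mean[idx]), 2, gs$sd[idx], `/`)
    zpred <- zpred + as.numeric(Xz %*% object$coefficients)
  }
  names(zpred) <- rownames(newdata)
  switch(scale,
         z = zpred,
         model = zpred * object$y_scale + object$y_center,
         native = {
           m <- zpred * object$y_scale + object$y_center
           if (object$transform == "log10") 10^m else m
         })
}

#' Leave-one-out cross-validated performance
#'
#' Each cell type is predicted by a model fit entirely without it: per-gene
#' scaling, response standardization and both fitting stages are re-run
#' inside every fold. Performance is the unity-line
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2} over the pooled
#' held-out predictions on the modeling scale; it can be negative.
#'
#' @inheritParams fit_two_stage
#' @return An object of class `model_evaluation`: `r2_loocv`,
#'   `predictions` (tibble: `cell_type`, `observed`, `predicted`, modeling
#'   scale), `property`.
#' @export
evaluate_loocv <- function(X, y, cfg = run_config(), property = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 8) stop("Need at least 8 cell types with observed values.", call. = FALSE)
  y_model <- if (is.null(property)) y else to_model_scale(y, property)
  preds <- vapply(seq_len(n), function(i) {
    fit <- fit_two_stage(X[-i, , drop = FALSE], y_model[-i], cfg)
    predict(fit, X[i, , drop = FALSE], scale = "model")
  }, numeric(1))
  sse <- sum((y_model - preds)^2)
  sst <- sum((y_model - mean(y_model))^2)
  structure(
    list(
      r2_loocv = 1 - sse / sst,
      predictions = tibble::tibble(
        cell_type = rownames(X) %||% as.character(seq_len(n)),
        observed = y_model, predicted = preds),
      property = property %||% NA_character_
    ),
    class = "model_evaluation"
  )
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s: LOOCV R^2 = %.3f over %d cell types\n",
              x$property, x$r2_loocv, nrow(x$predictions)))
  invisible(x)
}

#' Shuffled-label null for predictive performance
#'
#' Re-pairs the response with the expression rows at random (destroying
#' any real gene-ephys link while preserving each marginal) and re-runs
#' the full leave-one-out evaluation per replicate.
#'
#' @inheritParams fit_two_stage
#' @param n_shuffles Number of shuffle replicates.
#' @return Tibble with one row per replicate: `replicate`, `r2_shuffled`.
#' @export
shuffled_label_null <- function(X, y, cfg = run_config(), property = NULL,
                                n_shuffles = 10L) {
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  perms <- with_substream(cfg$seed, "shuffled_label_null", {
    replicate(n_shuffles, sample.int(length(y)), simplify = FALSE)
  })
  r2 <- vapply(perms, function(p) {
    evaluate_loocv(X, y[p], cfg, property)$r2_loocv
  }, numeric(1))
  tibble::tibble(replicate = seq_len(n_shuffles), r2_shuffled = r2)
}

#' Stratified bootstrap of predictive performance
#'
#' Per replicate: expression samples are resampled with replacement within
#' each cell type, ephys articles are resampled with replacement within
#' each (cell type, property), and the paired dataset is rebuilt through
#' the standard summarization pipeline before re-running the leave-one-out
#' evaluation. Stratification guarantees every cell type is present in
#' every replicate; a type with a single article simply yields that
#' article each draw.
#'
#' @param expr Sample-level [expression_matrix()] (post probe collapse /
#'   normalization).
#' @param records Preprocessed, condition-adjusted measurement tibble.
#' @param property Registered property code to model.
#' @param cfg A [run_config()] (supplies `n_bootstrap` and the seed).
#' @param thresholds Optional `gene_filter_thresholds` fixing the gene
#'   filter cutoffs across replicates; `NULL` re-derives them per
#'   replicate.
#' @return Tibble with one row per replicate: `replicate`, `r2_loocv`.
#' @export
bootstrap_performance <- function(expr, records, property, cfg = run_config(),
                                  thresholds = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  assert_property(property)
  df <- tibble::as_tibble(records)
  df <- df[df$property == property, ]
  labels <- expr$sample_meta$cell_type_label
  types <- unique(labels)
  art_by_type <- split(unique(df[, c("cell_type_label", "article_id")]),
                       unique(df[, c("cell_type_label", "article_id")])$cell_type_label)
  draws <- with_substream(cfg$seed, paste0("bootstrap_", property), {
    lapply(seq_len(cfg$n_bootstrap), function(b) {
      list(
        samples = unlist(lapply(types, function(t) {
          idx <- which(labels == t)
          sample(idx, length(idx), replace = TRUE)
        })),
        articles = lapply(art_by_type, function(a) {
          sample(a$article_id, nrow(a), replace = TRUE)
        })
      )
    })
  })
  r2 <- vapply(draws, function(d) {
    sub <- expr$values[, d$samples, drop = FALSE]
    colnames(sub) <- sprintf("bs%04d", seq_len(ncol(sub)))
    meta <- expr$sample_meta[d$samples, ]
    meta$sample_id <- colnames(sub)
    bexpr <- summarize_expression_by_cell_type(
      expression_matrix(sub, expr$scale, meta))
    filt <- if (is.null(thresholds)) {
      filter_genes(bexpr)
    } else {
      filter_genes(bexpr, thresholds$mu_global, thresholds$sigma_global)
    }
    brec <- dplyr::bind_rows(lapply(names(d$articles), function(t) {
      picked <- d$articles[[t]]
      dplyr::bind_rows(lapply(seq_along(picked), function(k) {
        rows <- df[df$cell_type_label == t & df$article_id == picked[k], ]
        rows$article_id <- sprintf("%s_bs%03d", rows$article_id, k)
        rows
      }))
    }))
    beph <- summarize_ephys_by_cell_type(brec)
    ds <- pair_by_label(filt$expression, beph)
    y <- ds$ephys[, property]
    evaluate_loocv(ds$expression, y, cfg, property)$r2_loocv
  }, numeric(1))
  tibble::tibble(replicate = seq_len(cfg$n_bootstrap), r2_loocv = r2)
}

#' Apply a discovery-trained model to an independently normalized dataset
#'
#' Validation expression is mapped to log2(TPM + 1) and z-scored per gene
#' within the validation dataset; validation ephys is registry-transformed
#' and z-scored within dataset. Because the model was trained on a
#' standardized response, predictions and observations share the
#' standardized scale. Two transfer metrics are reported: the squared
#' Pearson correlation between predicted and observed (the headline
#' metric, tolerant of affine miscalibration between the two
#' normalizations) and the unity-line form `1 - SSE/SST`.
#'
#' @param model A [fit_two_stage()] model trained on the discovery
#'   dataset.
#' @param val_expr Line x gene matrix or expression [celltype_matrix()] of
#'   the validation dataset, on the TPM scale (or already log2(TPM + 1);
#'   see `expr_scale`).
#' @param val_ephys Named numeric vector (or line x property matrix /
#'   ephys [celltype_matrix()]) of observed validation values in native
#'   units.
#' @param expr_scale Scale of `val_expr`: `"tpm"` (default; log2(TPM + 1)
#'   is applied) or `"log2"` (used as is).
#' @return An object of class `transfer_evaluation`: `predictions`
#'   (tibble: `cell_type`, `observed_z`, `predicted_z`), `r2_transfer`
#'   (squared Pearson correlation), `r2_transfer_unity`, `property`.
#' @export
transfer_predict <- function(model, val_expr, val_ephys,
                             expr_scale = c("tpm", "log2")) {
  stopifnot(inherits(model, "sparse_ephys_model"))
  expr_scale <- match.arg(expr_scale)
  X <- if (inherits(val_expr, "celltype_matrix")) val_expr$values else val_expr
  if (expr_scale == "tpm") X <- log2(X + 1)
  miss <- setdiff(model$selected_genes, colnames(X))
  if (length(miss) > 0) {
    stop("Model gene(s) absent from validation expression: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (inherits(val_ephys, "celltype_matrix")) val_ephys <- val_ephys$values
  prop <- model$property
  yv <- if (is.matrix(val_ephys)) val_ephys[, prop] else val_ephys
  yv <- yv[rownames(X)]
  ok <- !is.na(yv)
  if (sum(ok) < 3) stop("Fewer than 3 validation lines with observed values.",
                        call. = FALSE)
  X <- X[ok, , drop = FALSE]; yv <- yv[ok]
  y_model <- if (!is.na(prop)) to_model_scale(yv, prop) else yv
  y_z <- as.numeric(scale(y_model))

  # z-score within the validation dataset, then push through the model's
  # standardized coefficients directly (the model's own training scaling
  # belongs to the discovery scale)
  Xz <- standardize_columns(X)$X
  pred_z <- rep(model$intercept, nrow(Xz))
  if (length(model$selected_genes) > 0) {
    pred_z <- pred_z +
      as.numeric(Xz[, model$selected_genes, drop = FALSE] %*% model$coefficients)
  }
  sse <- sum((y_z - pred_z)^2)
  sst <- sum((y_z - mean(y_z))^2)
  r2p <- if (stats::sd(pred_z) == 0) 0 else stats::cor(pred_z, y_z)^2
  structure(
    list(
      predictions = tibble::tibble(
        cell_type = rownames(X), observed_z = y_z, predicted_z = pred_z),
      r2_transfer = r2p,
      r2_transfer_unity = 1 - sse / sst,
      property = prop
    ),
    class = "transfer_evaluation"
  )
}

#' @export
print.transfer_evaluation <- function(x, ...) {
  cat(sprintf("<transfer_evaluation> %s: transfer R^2 = %.3f (Pearson^2), %.3f (unity line), %d lines\n",
              x$property, x$r2_transfer, x$r2_transfer_unity,
              nrow(x$predictions)))
  invisible(x)
}
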