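#' Confusion matrix
#'
#' Rows are true labels, columns predicted; the label universe is the sorted
#' union of both vectors, so `trace / n` equals [accuracy()].
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return integer matrix of class `confusion_matrix` with dimnames
#'   `true` x `predicted`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors have different lengths")
  }
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  labs <- sort(unique(c(tl, pl)))
  cm <- unclass(table(factor(tl, levels = labs), factor(pl, levels = labs)))
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class classification report
#'
#' Per-class recall (the "accuracy score for each cluster": diagonal over row
#' total), precision (diagonal over column total; 0 with an `undefined` flag
#' when the class is never predicted), and support, plus the overall mean
#' accuracy (trace over n, i.e. sample-weighted) and the unweighted macro
#' mean of per-class recalls.
#'
#' @inheritParams confusion_matrix
#' @return Object of class `classification_report`: `per_class` data frame
#'   (`label`, `recall`, `precision`, `precision_undefined`, `support`),
#'   `overall_mean_accuracy`, `macro_mean_recall`, `n_samples`, `confusion`.
#' @export
classification_report <- function(true_labels, predicted_labels) {
  cm <- confusion_matrix(true_labels, predicted_labels)
  n <- sum(cm)
  support <- rowSums(cm)
  colsum <- colSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, NA_real_)
  precision <- ifelse(colsum > 0, diag(cm) / colsum, 0)
  structure(
    list(per_class = data.frame(label = rownames(cm), recall = recall,
                                precision = precision,
                                precision_undefined = colsum == 0,
                                support = as.integer(support),
                                row.names = NULL),
         overall_mean_accuracy = sum(diag(cm)) / n,
         macro_mean_recall = mean(recall, na.rm = TRUE),
         n_samples = as.integer(n), confusion = cm),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 4, ...) {
  cat(sprintf("<classification_report> n = %d, overall accuracy %.4f (macro recall %.4f)\n",
              x$n_samples, x$overall_mean_accuracy, x$macro_mean_recall))
  print(x$per_class, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Write a classification report and confusion matrix as delimited text
#'
#' @param report a [classification_report()].
#' @param dir output directory (created if absent); writes
#'   `classification_report.tsv`, `confusion_matrix.tsv`, `summary.json`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "classification_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$per_class,
                     file.path(dir, "classification_report.tsv"), sep = "\t")
  cm <- as.data.frame.matrix(report$confusion)
  cm <- cbind(true = rownames(cm), cm)
  data.table::fwrite(cm, file.path(dir, "confusion_matrix.tsv"), sep = "\t")
  jsonlite::write_json(
    list(n_samples = report$n_samples,
         overall_mean_accuracy = report$overall_mean_accuracy,
         macro_mean_recall = report$macro_mean_recall),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Scatter plot of samples in component space
#'
#' One point per sample, coloured by label; axis captions carry the component
#' index and, when supplied, its explained-variance fraction. With a single
#' available axis (the k = 2 discriminant case) the plot falls back to a 1-D
#' jittered strip.
#'
#' @param scores numeric matrix of coordinates (PC scores or discriminant
#'   coordinates).
#' @param labels per-sample labels (see [fit_lda()]), or `NULL` for unlabelled
#'   points.
#' @param axes pair of column indices to plot (or a single index for the 1-D
#'   fallback).
#' @param file output path; format from `format` or the file extension
#'   (`.png` or `.svg`).
#' @param explained_variance optional per-component variance fractions for
#'   the axis captions.
#' @param format `"png"` or `"svg"`; default inferred from `file`.
#' @param width,height,pointsize device parameters (pixels for PNG, inches
#'   for SVG).
#' @return `file`, invisibly.
#' @export
scatter_plot <- function(scores, labels = NULL, axes = c(1L, 2L), file,
                         explained_variance = NULL, format = NULL,
                         width = 800, height = 600, pointsize = 12) {
  scores <- as.matrix(scores)
  axes <- as.integer(axes)
  if (any(axes < 1L) || any(axes > ncol(scores))) {
    stop(sprintf("requested axes (%s) outside the %d available components",
                 paste(axes, collapse = ","), ncol(scores)))
  }
  format <- format %||% tolower(tools::file_ext(file))
  if (!format %in% c("png", "svg")) stop("format must be 'png' or 'svg'")
  y <- if (is.null(labels)) rep("sample", nrow(scores)) else {
    resolve_labels(labels, rownames(scores) %||% as.character(seq_len(nrow(scores))))
  }
  yf <- factor(y)
  pal <- grDevices::hcl.colors(max(3L, nlevels(yf)), palette = "Dark 3")[seq_len(nlevels(yf))]
  cap <- function(a) {
    if (!is.null(explained_variance) && a <= length(explained_variance)) {
      sprintf("Component %d (%.1f%%)", a, 100 * explained_variance[a])
    } else sprintf("Component %d", a)
  }
  if (format == "png") {
    grDevices::png(file, width = width, height = height, pointsize = pointsize)
  } else {
    grDevices::svg(file, width = width / 100, height = height / 100,
                   pointsize = pointsize)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  if (length(axes) == 1L || ncol(scores) == 1L) {
    a <- axes[1]
    set.seed(0)  # fixed jitter so output metadata is deterministic
    graphics::plot(scores[, a], jitter(as.integer(yf), amount = 0.15),
                   col = pal[as.integer(yf)], pch = 19, yaxt = "n",
                   xlab = cap(a), ylab = "", main = "Discriminant coordinates")
    graphics::axis(2, at = seq_len(nlevels(yf)), labels = levels(yf), las = 1)
  } else {
    graphics::plot(scores[, axes[1]], scores[, axes[2]],
                   col = pal[as.integer(yf)], pch = 19,
                   xlab = cap(axes[1]), ylab = cap(axes[2]),
                   main = "Sample coordinates")
    graphics::legend("topright", legend = levels(yf), col = pal, pch = 19,
                     cex = 0.8, bg = "white")
  }
  invisible(file)
}

MODEL_FORMAT <- "dapcr-model"
MODEL_VERSION <- 1L

mat_ser <- function(m) list(nrow = nrow(m), ncol = ncol(m),
                            data = as.numeric(m))
mat_deser <- function(x) matrix(as.numeric(unlist(x$data)),
                                nrow = x$nrow, ncol = x$ncol)

#' Serialize a fitted DAPC model to a portable archive
#'
#' The archive is a versioned JSON document of named numeric arrays plus fit
#' provenance — not a language-native object dump — so it can be inspected
#' and reloaded anywhere. Numbers are written at full precision; reloaded
#' models reproduce predictions and posteriors to better than 1e-12.
#'
#' @param model a fitted `dapc_model`.
#' @param path output path (conventionally `.dapcr.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dapc_model"))
  pc <- model$pc_model; da <- model$da_model
  doc <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    provenance = model$provenance,
    pc = list(r = pc$r, loadings = mat_ser(pc$loadings),
              singular_values = pc$singular_values,
              explained_variance_fraction = pc$explained_variance_fraction,
              center = pc$center, scale_ = pc$scale_,
              centering_mode = pc$centering_mode, n_fit = pc$n_fit),
    da = list(k = da$k, class_labels = da$class_labels,
              discriminant_axes = mat_ser(da$discriminant_axes),
              axis_eigenvalues = da$axis_eigenvalues,
              class_means = mat_ser(da$class_means),
              class_priors = da$class_priors,
              pooled_within_scatter = mat_ser(da$pooled_within_scatter)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a serialized DAPC model
#'
#' @param path archive written by [save_model()].
#' @return a `dapc_model`. Errors explicitly on a wrong format tag or an
#'   unsupported archive version; a truncated/tampered file fails JSON
#'   parsing.
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model archive (corrupt or truncated): ",
                         conditionMessage(e))
                  })
  if (!identical(doc$format, MODEL_FORMAT)) {
    stop("not a dapcr model archive: format tag '", doc$format %||% "<none>", "'")
  }
  if (!identical(as.integer(doc$version), MODEL_VERSION)) {
    stop(sprintf("model archive version %s is not supported by this package (expected %d)",
                 doc$version %||% "<none>", MODEL_VERSION))
  }
  pc <- structure(
    list(r = as.integer(doc$pc$r), loadings = mat_deser(doc$pc$loadings),
         singular_values = as.numeric(doc$pc$singular_values),
         explained_variance_fraction = as.numeric(doc$pc$explained_variance_fraction),
         center = if (is.null(doc$pc$center)) NULL else as.numeric(doc$pc$center),
         scale_ = if (is.null(doc$pc$scale_)) NULL else as.numeric(doc$pc$scale_),
         centering_mode = doc$pc$centering_mode,
         n_fit = as.integer(doc$pc$n_fit)),
    class = "pc_model")
  da <- structure(
    list(k = as.integer(doc$da$k),
         class_labels = as.character(doc$da$class_labels),
         discriminant_axes = mat_deser(doc$da$discriminant_axes),
         axis_eigenvalues = as.numeric(doc$da$axis_eigenvalues),
         class_means = mat_deser(doc$da$class_means),
         class_priors = as.numeric(doc$da$class_priors),
         pooled_within_scatter = mat_deser(doc$da$pooled_within_scatter)),
    class = "da_model")
  structure(list(pc_model = pc, da_model = da, provenance = doc$provenance),
            class = "dapc_model")
}
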