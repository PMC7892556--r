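# Subtype classification (per-gene standardization, merging, hierarchical
# clustering on a 36-gene signature, dendrogram cut in two) and the
# stiffness differential-expression stage (Log2+1, unpaired/paired t-tests,
# P <= 0.05 & FC > 1.2 filter) for the epithelial (human-array) and stromal
# (mouse-array) compartments of xenograft samples.

#' Expression dataset container
#'
#' @param mat numeric genes x samples matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param annotations data.frame with one row per sample: `sample_id`,
#'   `tumor_id`, `subtype`, `stiffness_class`, `region`, `compartment`.
#' @param scale `"linear"` or `"log2p1"` (the transform is applied at most
#'   once; the flag enforces that).
#' @return an `expression_dataset`.
#' @export
expression_dataset <- function(mat, annotations,
                               scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            anyDuplicated(rownames(mat)) == 0,
            identical(colnames(mat), annotations$sample_id))
  structure(list(mat = mat, annotations = annotations, scale = scale,
                 standardized = FALSE),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples [%s%s]\n",
              nrow(x$mat), ncol(x$mat), x$scale,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Signature gene set
#'
#' Exactly 36 unique gene ids split into a half correlated and a half
#' anti-correlated with miR-200a; the anti-correlated (stromal/Mesenchymal-up)
#' half drives the subtype labeling of the dendrogram cut.
#'
#' @param correlated,anticorrelated character vectors of gene ids; both
#'   non-empty, 36 unique ids in total.
#' @return a `signature_set`.
#' @export
signature_set <- function(correlated, anticorrelated) {
  ids <- c(correlated, anticorrelated)
  if (length(ids) != 36 || anyDuplicated(ids))
    stop("signature must contain exactly 36 unique gene ids")
  if (!length(correlated) || !length(anticorrelated))
    stop("both signature halves must be non-empty")
  structure(list(correlated = correlated, anticorrelated = anticorrelated),
            class = "signature_set")
}

#' Log2(x + 1) transform
#'
#' @param dataset an `expression_dataset` on linear scale, non-negative.
#' @return the dataset on log2p1 scale.
#' @export
log2p1 <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "linear") stop("data are already log-transformed")
  if (any(dataset$mat < 0)) stop("negative values on linear scale")
  dataset$mat <- log2(dataset$mat + 1)
  dataset$scale <- "log2p1"
  dataset
}

#' Per-gene standardization
#'
#' Centers and scales each gene row to mean 0 and unit sample SD within the
#' dataset; zero-variance genes are dropped with a warning. Standardizing an
#' already standardized dataset is a no-op up to numerical precision.
#'
#' @param dataset an `expression_dataset` with >= 2 samples.
#' @return the standardized dataset (gains `standardized = TRUE`).
#' @export
standardize_genes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"), ncol(dataset$mat) >= 2)
  m <- dataset$mat
  sds <- apply(m, 1, stats::sd)
  drop <- sds < 1e-12
  if (all(drop)) stop("all genes have zero variance")
  if (any(drop)) {
    warning(sum(drop), " zero-variance gene(s) dropped")
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  dataset$mat <- (m - rowMeans(m)) / sds
  dataset$standardized <- TRUE
  dataset
}

#' Merge two standardized datasets on their shared genes
#'
#' Column-wise concatenation restricted to shared gene ids; a `source`
#' provenance column is added to the annotations. Standardizing per gene
#' within each dataset before merging is what removes platform-level
#' technical artifacts.
#'
#' @param a,b standardized `expression_dataset`s (`b` may be NULL or empty).
#' @param min_shared minimum required gene overlap.
#' @return merged `expression_dataset`.
#' @export
merge_standardized <- function(a, b, min_shared = 36) {
  stopifnot(inherits(a, "expression_dataset"), a$standardized)
  a$annotations$source <- a$annotations$source %||% "A"
  if (is.null(b) || (inherits(b, "expression_dataset") && ncol(b$mat) == 0))
    return(a)
  stopifnot(inherits(b, "expression_dataset"), b$standardized,
            a$scale == b$scale)
  shared <- intersect(rownames(a$mat), rownames(b$mat))
  if (length(shared) < min_shared)
    stop("insufficient gene overlap: ", length(shared), " shared genes")
  ann_a <- a$annotations; ann_a$source <- ann_a$source %||% "A"
  ann_b <- b$annotations; ann_b$source <- "B"
  cols <- intersect(names(ann_a), names(ann_b))
  out <- expression_dataset(cbind(a$mat[shared, , drop = FALSE],
                                  b$mat[shared, , drop = FALSE]),
                            rbind(ann_a[cols], ann_b[cols]),
                            scale = a$scale)
  out$standardized <- TRUE
  out
}

#' Cluster samples into two molecular subtypes on the signature genes
#'
#' Agglomerative hierarchical clustering of samples on the 36-gene signature
#' submatrix (Euclidean distance, complete linkage), cut into two groups.
#' The group with the higher mean expression of the anti-correlated
#' (stromal/Mesenchymal-up) half is labeled Mesenchymal.
#'
#' @param dataset an `expression_dataset` (standardized values recommended).
#' @param signature a `signature_set`; all 36 genes must be present.
#' @return list with `hclust` (the dendrogram), `cluster` (integer 1/2 per
#'   sample) and `subtype` (character `"Mesenchymal"`/`"Non-Mesenchymal"`).
#' @export
cluster_subtypes <- function(dataset, signature) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(signature, "signature_set"))
  genes <- c(signature$correlated, signature$anticorrelated)
  missing <- setdiff(genes, rownames(dataset$mat))
  if (length(missing))
    stop("missing signature genes: ", paste(missing, collapse = ", "))
  if (ncol(dataset$mat) < 2) stop("need at least 2 samples")
  sub <- t(dataset$mat[genes, , drop = FALSE])  # samples x 36
  hc <- stats::hclust(stats::dist(sub, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2)
  anti_mean <- tapply(colMeans(dataset$mat[signature$anticorrelated,
                                           , drop = FALSE]), cl, mean)
  mes_cluster <- as.integer(names(which.max(anti_mean)))
  subtype <- ifelse(cl == mes_cluster, "Mesenchymal", "Non-Mesenchymal")
  list(hclust = hc, cluster = unname(cl),
       subtype = unname(subtype), sample_id = colnames(dataset$mat))
}

# Vectorized per-gene two-sample t (equal-variance Student or Welch).
row_t_unpaired <- function(xa, xb, var_equal = TRUE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  list(delta = ma - mb, t = t,
       p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
}

# Vectorized per-gene paired t on matched columns (A - B).
row_t_paired <- function(xa, xb) {
  d <- xa - xb
  n <- ncol(d)
  md <- rowMeans(d)
  sd_d <- sqrt(rowSums((d - md)^2) / (n - 1))
  t <- md / (sd_d / sqrt(n))
  list(delta = md, t = t,
       p = 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE))
}

#' Per-gene differential expression between two groups
#'
#' Student t-test on log2 values: equal-variance unpaired by default (a flag
#' switches to Welch), or paired on tumor-matched samples when `paired_by`
#' names the pairing annotation. Fold change is `2^|mean log2 difference|`
#' with the direction carried separately; a gene passes the filter when
#' `p <= 0.05` and `FC > 1.2` (no multiple-testing correction, by design).
#'
#' @param dataset an `expression_dataset` on log2p1 scale.
#' @param group_a,group_b character vectors of sample ids (disjoint, >= 2
#'   samples each).
#' @param paired_by optional annotation column (e.g. `"tumor_id"`); both
#'   groups must then pair completely one-to-one.
#' @param var_equal equal-variance Student t (TRUE, default) or Welch.
#' @param p_cut,fc_cut filter thresholds.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` by default (an extension, off by default: the filter gates on
#'   the raw p).
#' @return data.frame: `gene_id`, `t`, `p`, `p_adj`, `mean_log2_diff`, `fc`,
#'   `direction` (`"up"` = higher in group A), `pass`.
#' @export
differential_expression <- function(dataset, group_a, group_b,
                                    paired_by = NULL, var_equal = TRUE,
                                    p_cut = 0.05, fc_cut = 1.2,
                                    adjust = "none") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "log2p1")
    stop("differential expression expects log2p1-scale data")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  xa <- dataset$mat[, group_a, drop = FALSE]
  xb <- dataset$mat[, group_b, drop = FALSE]
  if (!is.null(paired_by)) {
    key <- dataset$annotations[[paired_by]]
    names(key) <- dataset$annotations$sample_id
    ka <- key[group_a]; kb <- key[group_b]
    if (anyDuplicated(ka) || anyDuplicated(kb) || !setequal(ka, kb))
      stop("incomplete pairing on '", paired_by, "'")
    xb <- xb[, match(ka, kb), drop = FALSE]
    res <- row_t_paired(xa, xb)
  } else {
    res <- row_t_unpaired(xa, xb, var_equal = var_equal)
  }
  p_adj <- stats::p.adjust(res$p, method = adjust)
  fc <- 2^abs(res$delta)
  data.frame(gene_id = rownames(dataset$mat),
             t = res$t, p = res$p, p_adj = p_adj,
             mean_log2_diff = res$delta, fc = fc,
             direction = ifelse(res$delta >= 0, "up", "down"),
             pass = !is.na(res$p) & p_adj <= p_cut & fc > fc_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split passing genes into up- and down-regulated lists
#'
#' @param de a [differential_expression()] table.
#' @return list `up`, `down` (character vectors) and `counts`.
#' @export
filter_de <- function(de) {
  up <- de$gene_id[de$pass & de$direction == "up"]
  down <- de$gene_id[de$pass & de$direction == "down"]
  list(up = up, down = down,
       counts = c(up = length(up), down = length(down), tested = nrow(de)))
}

# Sample ids for a (stiffness_class, region) condition of one compartment.
select_samples <- function(ann, stiffness, region = NULL) {
  sel <- ann$stiffness_class == stiffness
  if (!is.null(region)) sel <- sel & ann$region == region
  ann$sample_id[sel]
}

#' The six stiffness contrasts, per compartment
#'
#' For each compartment dataset (human probes = epithelium, mouse probes =
#' stroma): stiff-center versus soft and stiff-periphery versus soft
#' (unpaired), and center versus periphery within stiff tumors (paired by
#' tumor). Stiff tumors lacking one region are dropped from the paired
#' contrast with a warning.
#'
#' @param human,mouse `expression_dataset`s on log2p1 scale with complete
#'   annotations (`stiffness_class`, `region`, `tumor_id`).
#' @param ... options passed to [differential_expression()].
#' @return named list of six elements (`epithelium_center_vs_soft`, ...),
#'   each with the DE table (`table`) and the filtered `up`/`down` lists.
#' @export
de_contrast_suite <- function(human, mouse, ...) {
  one_compartment <- function(ds, label) {
    ann <- ds$annotations
    need <- c("stiffness_class", "region", "tumor_id")
    if (!all(need %in% names(ann)))
      stop("missing annotation columns: ",
           paste(setdiff(need, names(ann)), collapse = ", "))
    soft <- select_samples(ann, "soft")
    ctr <- select_samples(ann, "stiff", "center")
    per <- select_samples(ann, "stiff", "periphery")
    # paired contrast: keep only tumors with both regions
    tum_c <- ann$tumor_id[match(ctr, ann$sample_id)]
    tum_p <- ann$tumor_id[match(per, ann$sample_id)]
    both <- intersect(tum_c, tum_p)
    if (length(both) < length(union(tum_c, tum_p)))
      warning(label, ": tumor(s) lacking one region dropped from the paired contrast")
    contrasts <- list(
      center_vs_soft = differential_expression(ds, ctr, soft, ...),
      periphery_vs_soft = differential_expression(ds, per, soft, ...),
      center_vs_periphery = differential_expression(
        ds, ctr[tum_c %in% both], per[tum_p %in% both],
        paired_by = "tumor_id", ...))
    lapply(contrasts, function(tab) c(list(table = tab), filter_de(tab)))
  }
  c(stats::setNames(one_compartment(human, "epithelium"),
                    paste0("epithelium_", c("center_vs_soft",
                                            "periphery_vs_soft",
                                            "center_vs_periphery"))),
    stats::setNames(one_compartment(mouse, "stroma"),
                    paste0("stroma_", c("center_vs_soft",
                                        "periphery_vs_soft",
                                        "center_vs_periphery"))))
}
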