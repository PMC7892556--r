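# Synthetic two-compartment expression data: a human (epithelium) and a
# mouse (stroma) matrix over the same xenograft samples, with a planted
# 36-gene subtype signature, planted stromal DE genes, and center/periphery
# pairing within stiff tumors. Values are emitted on the linear scale as
# 2^x - 1 so that the downstream Log2+1 transform recovers the simulated
# log2 values exactly.

#' A placeholder 36-gene signature for synthetic data
#'
#' 18 ids correlated and 18 anti-correlated with miR-200a. Any user-provided
#' signature can be substituted via [read_signature()].
#'
#' @return a `signature_set`.
#' @export
synthetic_signature <- function() {
  signature_set(correlated = sprintf("SIGC%02d", 1:18),
                anticorrelated = sprintf("SIGA%02d", 1:18))
}

#' Generate paired human/mouse expression datasets with ground truth
#'
#' Tumors: `n_mes` Mesenchymal and `n_nonmes` Non-Mesenchymal. A fraction of
#' the Mesenchymal tumors are stiff and contribute a paired center and
#' periphery sample; all other tumors are soft and contribute a single
#' (center-dissected) sample. The 36 signature genes are shifted by
#' `signature_effect_sd` within-gene SDs between subtypes in the human
#' (epithelium) matrix: the anti-correlated half up in Mesenchymal samples,
#' the correlated half up in Non-Mesenchymal samples. The mouse (stroma)
#' matrix carries `n_de` planted DE genes raised by `de_log2fc` log2 units in
#' stiff-center samples (relative to both soft tumors and stiff peripheries).
#'
#' @param n_mes,n_nonmes tumor counts per subtype.
#' @param n_genes genes per matrix (>= 36 + n_de).
#' @param signature_effect_sd subtype separation in units of the within-group
#'   SD (0 gives a negative control where classification is at chance).
#' @param n_de number of planted stromal DE genes.
#' @param de_log2fc planted log2 fold change.
#' @param noise_sd within-group SD on the log2 scale.
#' @param frac_stiff fraction of Mesenchymal tumors that are stiff.
#' @param seed integer seed.
#' @return list `human`, `mouse` (linear-scale `expression_dataset`s) and
#'   `truth` (subtype labels, signature with effects, DE list, pairing map).
#' @export
generate_expression_dataset <- function(n_mes = 8L, n_nonmes = 8L,
                                        n_genes = 2000L,
                                        signature_effect_sd = 2,
                                        n_de = 50L, de_log2fc = 1,
                                        noise_sd = 0.25, frac_stiff = 0.5,
                                        seed = 1L) {
  if (n_genes < 36 + n_de)
    stop("n_genes must be at least 36 + n_de")
  if (n_mes < 1 || n_nonmes < 1) stop("need at least one tumor per subtype")
  sig <- synthetic_signature()
  sig_ids <- c(sig$correlated, sig$anticorrelated)
  de_ids <- if (n_de > 0) sprintf("DE%04d", seq_len(n_de)) else character(0)
  other <- sprintf("G%05d", seq_len(n_genes - 36 - n_de))
  genes <- c(sig_ids, de_ids, other)

  n_stiff <- max(1L, round(n_mes * frac_stiff))
  tumors <- data.frame(
    tumor_id = sprintf("T%02d", seq_len(n_mes + n_nonmes)),
    subtype = rep(c("Mesenchymal", "Non-Mesenchymal"), c(n_mes, n_nonmes)),
    stiffness_class = c(rep(c("stiff", "soft"), c(n_stiff, n_mes - n_stiff)),
                        rep("soft", n_nonmes)),
    stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(nrow(tumors)), function(i) {
    tm <- tumors[i, ]
    regions <- if (tm$stiffness_class == "stiff") c("center", "periphery")
               else "center"  # soft tumors: only the center is dissected
    data.frame(sample_id = sprintf("%s_%s", tm$tumor_id, substr(regions, 1, 1)),
               tumor_id = tm$tumor_id, subtype = tm$subtype,
               stiffness_class = tm$stiffness_class, region = regions,
               stringsAsFactors = FALSE)
  }))
  ns <- nrow(ann)

  withr::with_seed(mix_seed(seed, 501), {
    mu <- stats::runif(n_genes, 3, 8)  # baseline log2 abundance per gene
    make_mat <- function(planted) {
      x <- matrix(stats::rnorm(n_genes * ns, 0, noise_sd), n_genes, ns,
                  dimnames = list(genes, ann$sample_id)) + mu + planted
      2^x - 1
    }
    # human / epithelium: subtype signature
    planted_h <- matrix(0, n_genes, ns, dimnames = list(genes, ann$sample_id))
    is_mes <- ann$subtype == "Mesenchymal"
    shift <- signature_effect_sd * noise_sd
    planted_h[sig$anticorrelated, is_mes] <- shift
    planted_h[sig$correlated, !is_mes] <- shift
    # mouse / stroma: DE genes up in stiff centers
    planted_m <- matrix(0, n_genes, ns, dimnames = list(genes, ann$sample_id))
    stiff_center <- ann$stiffness_class == "stiff" & ann$region == "center"
    planted_m[de_ids, stiff_center] <- de_log2fc
    human <- expression_dataset(make_mat(planted_h),
                                cbind(ann, compartment = "epithelium"),
                                scale = "linear")
    mouse <- expression_dataset(make_mat(planted_m),
                                cbind(ann, compartment = "stroma"),
                                scale = "linear")
    stiff_ann <- ann[ann$stiffness_class == "stiff", ]
    pairing <- data.frame(
      tumor_id = unique(stiff_ann$tumor_id),
      center_sample = stiff_ann$sample_id[stiff_ann$region == "center"],
      periphery_sample = stiff_ann$sample_id[stiff_ann$region == "periphery"],
      stringsAsFactors = FALSE)
    truth <- list(
      samples = ann,
      signature = sig,
      signature_effect_sd = signature_effect_sd,
      de_genes = data.frame(gene_id = de_ids,
                            true_log2fc = rep(de_log2fc, n_de),
                            stringsAsFactors = FALSE),
      pairing = pairing,
      seed = seed)
    list(human = human, mouse = mouse, truth = truth)
  })
}
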