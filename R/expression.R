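# Expression-based gene classification.
#
# Genes are classified from log2 expression matrices of two genotypes
# (wild-type Col-0 and the npr1-1 mutant) x two treatments (control,
# salicylic acid) x replicates:
#   SI  - SA-induced:   Col-0 log2 fold change >= 2 with p <= 0.05
#   SR  - SA-repressed: Col-0 log2 fold change <= -2 with p <= 0.05
#   SIL - silent:       every Col-0 value <= 0 in all replicates/treatments
#   CON - constitutive: every Col-0 value >= 3 in all replicates/treatments
# NPR1 dependence is read from a per-gene two-way ANOVA (genotype x
# treatment): a gene is SA-regulated when its treatment-effect q-value is
# <= 0.05, NPR1-dependent (ND) when the dependence p is <= 1e-4 and
# NPR1-independent (NI) when it is >= 0.1; dependence defaults to the
# genotype x treatment interaction term.

#' Read a long-format expression matrix
#'
#' TSV with header `gene_id genotype treatment replicate value`; genotype
#' in {Col0, npr1}, treatment in {control, SA}, value in log2 units.
#'
#' @param path file path.
#' @return data.frame in long format.
#' @export
read_expression <- function(path) {
  e <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "genotype", "treatment", "replicate", "value")
  miss <- setdiff(need, names(e))
  if (length(miss) > 0)
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  e
}

#' Write a long-format expression matrix
#' @param expr long-format expression data.frame.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# two-sample Student's t (equal-variance); zero-variance conventions as in
# window_significance
two_sample_t <- function(a, b) {
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = Inf, p = .Machine$double.xmin))
  }
  se <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
  tt <- (mean(a) - mean(b)) / se
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = length(a) + length(b) - 2))
}

#' Treatment contrast and differential-expression p for one gene in Col-0
#'
#' log2 fold change is mean(SA) - mean(control) over Col-0 replicates; the
#' p-value is a two-sample Student's t between the two treatment groups.
#'
#' @param gene_expr long-format rows for one gene.
#' @return list with `log2_fc`, `p_de`.
#' @export
sa_contrast <- function(gene_expr) {
  w <- gene_expr[gene_expr$genotype == "Col0", ]
  ctl <- w$value[w$treatment == "control"]
  sa <- w$value[w$treatment == "SA"]
  if (length(ctl) == 0 || length(sa) == 0)
    stop("missing Col0 control or SA replicates for gene ",
         gene_expr$gene_id[1])
  tt <- two_sample_t(sa, ctl)
  list(log2_fc = mean(sa) - mean(ctl), p_de = tt$p)
}

#' Classify a gene's SA response
#' @param log2_fc Col-0 treatment contrast (log2 units).
#' @param p_de differential-expression p-value.
#' @param fc_up,fc_down log2 fold-change cutoffs (defaults +2 / -2,
#'   inclusive).
#' @param p_max significance cutoff (default 0.05).
#' @return `"SI"`, `"SR"` or `"none"`.
#' @export
classify_sa_response <- function(log2_fc, p_de, fc_up = 2, fc_down = -2,
                                 p_max = 0.05) {
  if (is.na(p_de)) stop("missing differential-expression p-value")
  if (log2_fc >= fc_up && p_de <= p_max) return("SI")
  if (log2_fc <= fc_down && p_de <= p_max) return("SR")
  "none"
}

#' Classify a gene's baseline expression as silent or constitutive
#'
#' Requires a consistent profile over every Col-0 replicate of both
#' treatments: all values `<= sil_max` for silent (SIL), all `>= con_min`
#' for constitutive (CON). Genes already called SI/SR are excluded by the
#' caller.
#'
#' @param values_col0 all Col-0 log2 values (control and SA replicates).
#' @param sil_max silent ceiling (default 0).
#' @param con_min constitutive floor (default 3).
#' @return `"SIL"`, `"CON"` or `"none"`.
#' @export
classify_baseline <- function(values_col0, sil_max = 0, con_min = 3) {
  if (all(values_col0 <= sil_max)) return("SIL")
  if (all(values_col0 >= con_min)) return("CON")
  "none"
}

#' Two-way fixed-effects ANOVA for a balanced 2x2 design
#'
#' Classical sums-of-squares decomposition of per-gene log2 expression over
#' genotype x treatment with r replicates per cell: F = MS_effect/MS_error
#' with df (1, 4(r-1)). With zero error variance the result is flagged
#' degenerate and p is resolved by the effect sum of squares (0 if the
#' effect is real, 1 if absent), so noise-free planted designs classify
#' exactly.
#'
#' @param value numeric response values.
#' @param genotype,treatment factors (two levels each), same length.
#' @return list with per-term `ss`, `F`, `p` for `genotype`, `treatment`,
#'   `interaction`, plus `ss_error`, `df_error`, `degenerate`.
#' @export
anova_two_way <- function(value, genotype, treatment) {
  genotype <- factor(genotype)
  treatment <- factor(treatment)
  if (nlevels(genotype) != 2 || nlevels(treatment) != 2)
    stop("a 2x2 design is required")
  n_cell <- table(genotype, treatment)
  if (length(unique(as.vector(n_cell))) != 1)
    stop("unbalanced design: equal replicates per cell are required")
  r <- as.vector(n_cell)[1]
  if (r < 2) stop("at least two replicates per cell are required")

  grand <- mean(value)
  mean_g <- tapply(value, genotype, mean)
  mean_t <- tapply(value, treatment, mean)
  mean_gt <- tapply(value, list(genotype, treatment), mean)
  ss_g <- 2 * r * sum((mean_g - grand)^2)
  ss_t <- 2 * r * sum((mean_t - grand)^2)
  ss_cells <- r * sum((mean_gt - grand)^2)
  ss_int <- ss_cells - ss_g - ss_t
  fitted <- mean_gt[cbind(as.integer(genotype), as.integer(treatment))]
  ss_err <- sum((value - fitted)^2)
  df_err <- 4 * (r - 1)
  ms_err <- ss_err / df_err

  one_term <- function(ss) {
    if (ms_err > 0) {
      f <- ss / ms_err
      list(ss = ss, F = f, p = stats::pf(f, 1, df_err, lower.tail = FALSE))
    } else if (ss > 0) {
      list(ss = ss, F = Inf, p = 0)
    } else {
      list(ss = ss, F = 0, p = 1)
    }
  }
  # numerical floor: interaction SS can be a tiny negative round-off
  ss_int <- max(ss_int, 0)
  list(genotype = one_term(ss_g), treatment = one_term(ss_t),
       interaction = one_term(ss_int),
       ss_error = ss_err, df_error = df_err, degenerate = ms_err == 0)
}

#' Classify NPR1 dependence of an SA-regulated gene
#'
#' @param q_treatment q-value of the ANOVA treatment effect (SA regulation).
#' @param p_dependence p-value of the dependence term (interaction by
#'   default).
#' @param log2_fc Col-0 treatment contrast, used to split SI vs SR.
#' @param q_reg_max SA-regulation cutoff (default 0.05).
#' @param p_nd_max NPR1-dependent ceiling (default 1e-4).
#' @param p_ni_min NPR1-independent floor (default 0.1).
#' @param fc_up,fc_down fold-change cutoffs for the SI/SR split.
#' @return one of `"SI-ND"`, `"SR-ND"`, `"SI-NI"`, `"SR-NI"`,
#'   `"unclassified"`.
#' @export
classify_npr1_dependence <- function(q_treatment, p_dependence, log2_fc,
                                     q_reg_max = 0.05, p_nd_max = 1e-4,
                                     p_ni_min = 0.1, fc_up = 2,
                                     fc_down = -2) {
  if (is.na(q_treatment) || is.na(p_dependence)) return("unclassified")
  if (q_treatment > q_reg_max) return("unclassified")
  if (is.na(log2_fc))
    stop("missing Col-0 fold change for an SA-regulated gene")
  dep <- if (p_dependence <= p_nd_max) "ND"
         else if (p_dependence >= p_ni_min) "NI"
         else return("unclassified")
  dir <- if (log2_fc >= fc_up) "SI"
         else if (log2_fc <= fc_down) "SR"
         else return("unclassified")
  paste(dir, dep, sep = "-")
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg (default) or Storey's q-value with a fixed lambda.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @param lambda Storey tuning parameter (default 0.5).
#' @return q-values, monotone over the sorted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q_bh <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  if (method == "BH") return(q_bh)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * q_bh)
}

#' Classify all genes of an expression matrix
#'
#' Runs the SA-response call, the SIL/CON baseline call and the per-gene
#' two-way ANOVA, adjusts the treatment-effect p-values across genes, and
#' assigns the NPR1-dependence subclass to SA-regulated genes.
#'
#' @param expr long-format expression data.frame (see [read_expression()]).
#' @param dependence_term ANOVA term supplying the NPR1-dependence p:
#'   `"interaction"` (default) or `"genotype"`.
#' @param method multiple-testing adjustment for the treatment effect.
#' @param ... thresholds forwarded to the classifiers.
#' @return data.frame `gene_id, log2_fc, p_de, p_treatment, q_treatment,
#'   p_dependence, class, subclass`.
#' @export
classify_genes <- function(expr, dependence_term = c("interaction",
                                                     "genotype"),
                           method = "BH", ...) {
  dependence_term <- match.arg(dependence_term)
  ids <- unique(expr$gene_id)
  rows <- lapply(ids, function(id) {
    ge <- expr[expr$gene_id == id, ]
    ct <- sa_contrast(ge)
    an <- anova_two_way(ge$value, ge$genotype, ge$treatment)
    data.frame(gene_id = id, log2_fc = ct$log2_fc, p_de = ct$p_de,
               p_treatment = an$treatment$p,
               p_dependence = an[[dependence_term]]$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_treatment <- adjust_pvalues(out$p_treatment, method = method)
  out$class <- NA_character_
  out$subclass <- NA_character_
  for (i in seq_len(nrow(out))) {
    id <- out$gene_id[i]
    ge <- expr[expr$gene_id == id, ]
    cls <- classify_sa_response(out$log2_fc[i], out$p_de[i], ...)
    if (cls == "none")
      cls <- classify_baseline(ge$value[ge$genotype == "Col0"])
    out$class[i] <- cls
    out$subclass[i] <- classify_npr1_dependence(
      out$q_treatment[i], out$p_dependence[i], out$log2_fc[i])
  }
  out[, c("gene_id", "log2_fc", "p_de", "p_treatment", "q_treatment",
          "p_dependence", "class", "subclass")]
}
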