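#' Expression set container for the six-condition priming design
#'
#' Holds a probes x samples matrix of linear-scale expression values with
#' sample metadata (condition, replicate pool) and optional detection
#' calls. The condition scheme follows the low/high-dose time-course
#' design: untreated `Control`, low dose `LD`, high dose at 3 and 24 hours
#' (`HD3`, `HD24`) and low-then-high dose at the same time points
#' (`LDHD3`, `LDHD24`).
#'
#' @param exprs numeric matrix (probes x samples), finite and positive,
#'   unique rownames (probe ids).
#' @param samples data.frame with one row per column of `exprs`: columns
#'   `condition` (one of the six levels) and `pool` (replicate pool id).
#' @param probes optional data.frame with columns `probe_id` and
#'   `gene_symbol`; defaults to probe ids as symbols.
#' @param calls optional character matrix like `exprs` with entries
#'   `"P"`/`"A"`/`"M"` (Present/Absent/Marginal).
#' @return object of class `expression_set`.
#' @export
expression_set <- function(exprs, samples, probes = NULL, calls = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs))) stop("exprs needs probe ids as rownames")
  if (anyDuplicated(rownames(exprs))) stop("duplicate probe ids")
  if (!all(is.finite(exprs)) || any(exprs <= 0))
    stop("expression values must be finite and positive (linear scale)")
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(exprs),
            all(c("condition", "pool") %in% names(samples)))
  bad <- setdiff(unique(as.character(samples$condition)), priming_conditions())
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  samples$condition <- factor(as.character(samples$condition), levels = priming_conditions())
  if (is.null(samples$sample_id)) samples$sample_id <- colnames(exprs)
  if (is.null(probes))
    probes <- data.frame(probe_id = rownames(exprs), gene_symbol = rownames(exprs),
                         stringsAsFactors = FALSE)
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    stopifnot(all(dim(calls) == dim(exprs)))
    if (!all(calls %in% c("P", "A", "M")))
      stop("detection calls must be 'P', 'A' or 'M'")
    rownames(calls) <- rownames(exprs)
  }
  structure(list(exprs = exprs, samples = samples, probes = probes, calls = calls),
            class = "expression_set")
}

#' The six condition labels of the priming design
#' @return character vector of condition levels.
#' @export
priming_conditions <- function() c("Control", "LD", "HD3", "HD24", "LDHD3", "LDHD24")

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set>", nrow(x$exprs), "probes x", ncol(x$exprs), "samples;",
      "conditions:", paste(levels(droplevels(x$samples$condition)), collapse = ", "),
      if (is.null(x$calls)) "(no detection calls)" else "(with detection calls)", "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$exprs)

# subset probes, keeping metadata aligned
es_subset <- function(es, keep) {
  structure(list(exprs = es$exprs[keep, , drop = FALSE],
                 samples = es$samples,
                 probes = es$probes[match(rownames(es$exprs)[keep] -> ids, es$probes$probe_id), ,
                                    drop = FALSE],
                 calls = if (is.null(es$calls)) NULL else es$calls[keep, , drop = FALSE]),
            class = "expression_set")
}

cond_cols <- function(es, condition) which(as.character(es$samples$condition) == condition)

#' Detection-call filter
#'
#' Removes probes that have no Present call in any replicate pool of any
#' condition (i.e. probes never reliably detected). Probe order is
#' preserved. When the set carries no detection calls the filter is the
#' identity, with a warning.
#'
#' @param es an `expression_set`.
#' @return filtered `expression_set`.
#' @export
present_call_filter <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  if (is.null(es$calls)) {
    warning("no detection calls available; present-call filter is a no-op")
    return(es)
  }
  keep <- rowSums(es$calls == "P") >= 1L
  es_subset(es, keep)
}

#' Comparison specification
#'
#' @param numerator,denominator condition labels.
#' @param fc fold-change threshold (default 2).
#' @param p adjusted-p threshold (default 0.05).
#' @return object of class `comparison_spec`.
#' @export
comparison_spec <- function(numerator, denominator = "Control", fc = 2, p = 0.05) {
  stopifnot(fc > 0, p > 0,
            numerator %in% priming_conditions(), denominator %in% priming_conditions())
  structure(list(numerator = numerator, denominator = denominator, fc = fc, p = p),
            class = "comparison_spec")
}

#' The five treatment-versus-control comparisons of the screening pipeline
#' @param fc,p thresholds applied to each comparison.
#' @return list of `comparison_spec`s.
#' @export
default_comparisons <- function(fc = 2, p = 0.05) {
  lapply(c("LD", "HD3", "HD24", "LDHD3", "LDHD24"),
         comparison_spec, denominator = "Control", fc = fc, p = p)
}

#' Per-gene fold change between two conditions
#'
#' Fold change is the ratio of the mean of the numerator replicates to the
#' mean of the denominator replicates on the linear scale; `direction` is
#' +1 for induction (FC >= 1) and -1 for reduction.
#'
#' @param es an `expression_set`.
#' @param spec a `comparison_spec` (its thresholds are not applied here).
#' @return data.frame with columns `probe_id`, `fc`, `direction`.
#' @export
fold_change <- function(es, spec) {
  a <- cond_cols(es, spec$numerator); b <- cond_cols(es, spec$denominator)
  if (!length(a)) stop("condition '", spec$numerator, "' absent from matrix")
  if (!length(b)) stop("condition '", spec$denominator, "' absent from matrix")
  num <- rowMeans(es$exprs[, a, drop = FALSE])
  den <- rowMeans(es$exprs[, b, drop = FALSE])
  if (any(den == 0)) stop("zero denominator mean")
  fc <- num / den
  data.frame(probe_id = rownames(es$exprs), fc = fc,
             direction = ifelse(fc >= 1, 1L, -1L), row.names = NULL)
}

#' Welch's two-sample t-test p-value
#'
#' Two-sided unequal-variance t-test via the Welch-Satterthwaite
#' approximation. In the screening pipeline it is applied to
#' log2-transformed intensities. Degenerate inputs follow the conventions:
#' both groups constant with equal means gives p = 1; unequal means with
#' zero variance in both groups gives the p = 0 limit (with a warning).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return two-sided p-value.
#' @examples
#' welch_test(c(10.1, 10.2, 9.9), c(12.0, 12.3, 11.8))
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(1)
    warning("zero variance in both groups with unequal means; p = 0 limit")
    return(0)
  }
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) + (vb / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# vectorised row-wise Welch test on log2 values between two column sets
row_welch <- function(mat, cols_a, cols_b) {
  la <- log2(mat[, cols_a, drop = FALSE]); lb <- log2(mat[, cols_b, drop = FALSE])
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1); vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: all replicates identical in both groups
  degen <- se2 == 0
  if (any(degen)) p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (wraps [stats::p.adjust()] with
#' `method = "BH"`).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression table for all screening comparisons
#'
#' For each comparison computes the linear fold change and the Welch
#' p-value on log2 intensities. Following the screening order -- the
#' 2-fold filter precedes the statistical testing -- the
#' Benjamini-Hochberg adjustment is computed within the fold-change
#' survivors: probes with at least a 2-fold change (either direction) in
#' at least one of the five treatment-vs-Control comparisons. Probes
#' outside that population get an adjusted p of 1; their raw p-values are
#' still reported. Besides the five treatment-vs-Control comparisons, the
#' two matched-time LD+HD-vs-HD comparisons used for readout
#' identification and mechanism roles are included (adjusted within the
#' same population).
#'
#' @param es an `expression_set` (normally after [present_call_filter()]).
#' @param filter_fc fold-change threshold defining the tested population
#'   (default 2).
#' @return named list of data.frames (one per comparison: `LD`, `HD3`,
#'   `HD24`, `LDHD3`, `LDHD24` vs Control; `LDHD3_vs_HD3`,
#'   `LDHD24_vs_HD24`), each with `probe_id`, `fc`, `p`, `padj`.
#' @export
de_table <- function(es, filter_fc = 2) {
  stopifnot(inherits(es, "expression_set"))
  pairs <- list(LD = c("LD", "Control"), HD3 = c("HD3", "Control"),
                HD24 = c("HD24", "Control"), LDHD3 = c("LDHD3", "Control"),
                LDHD24 = c("LDHD24", "Control"),
                LDHD3_vs_HD3 = c("LDHD3", "HD3"),
                LDHD24_vs_HD24 = c("LDHD24", "HD24"))
  raw <- lapply(pairs, function(pr) {
    ca <- cond_cols(es, pr[1]); cb <- cond_cols(es, pr[2])
    if (length(ca) < 2 || length(cb) < 2)
      stop("need >= 2 replicates of '", pr[1], "' and '", pr[2], "'")
    fc <- rowMeans(es$exprs[, ca, drop = FALSE]) / rowMeans(es$exprs[, cb, drop = FALSE])
    list(fc = fc, p = row_welch(es$exprs, ca, cb))
  })
  tested <- Reduce(`|`, lapply(raw[c("LD", "HD3", "HD24", "LDHD3", "LDHD24")],
                               function(d) d$fc >= filter_fc | d$fc <= 1 / filter_fc))
  lapply(raw, function(d) {
    padj <- rep(1, length(d$p))
    padj[tested] <- bh_fdr(d$p[tested])
    data.frame(probe_id = rownames(es$exprs), fc = d$fc, p = d$p,
               padj = padj, row.names = NULL)
  })
}

sig_up <- function(d, fc = 2, alpha = 0.05) d$fc >= fc & d$padj < alpha
sig_down <- function(d, fc = 2, alpha = 0.05) d$fc <= 1 / fc & d$padj < alpha
sig_any <- function(d, fc = 2, alpha = 0.05) sig_up(d, fc, alpha) | sig_down(d, fc, alpha)

#' Probes with non-trivial dynamics
#'
#' A probe is non-trivial when it shows a significant change (fold change
#' at least `fc` in either direction and adjusted p below `alpha`) in at
#' least one of the five treatment-vs-Control comparisons. Run after
#' [present_call_filter()].
#'
#' @param es an `expression_set`.
#' @param de optional precomputed [de_table()].
#' @param fc fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of probe ids.
#' @export
select_nontrivial <- function(es, de = de_table(es), fc = 2, alpha = 0.05) {
  hit <- Reduce(`|`, lapply(de[c("LD", "HD3", "HD24", "LDHD3", "LDHD24")],
                            sig_any, fc = fc, alpha = alpha))
  rownames(es$exprs)[hit]
}

#' Low-dose response class per probe
#'
#' `LD-induced` when LD vs Control has fold change >= `fc` and adjusted
#' p < `alpha`; `LD-reduced` when fold change <= 1/`fc` and significant;
#' `LD-silent` otherwise.
#'
#' @inheritParams select_nontrivial
#' @return factor (levels LD-induced, LD-reduced, LD-silent) named by
#'   probe id.
#' @export
classify_ld_response <- function(es, de = de_table(es), fc = 2, alpha = 0.05) {
  d <- de$LD
  cls <- rep("LD-silent", nrow(d))
  cls[sig_up(d, fc, alpha)] <- "LD-induced"
  cls[sig_down(d, fc, alpha)] <- "LD-reduced"
  factor(stats::setNames(cls, d$probe_id),
         levels = c("LD-induced", "LD-reduced", "LD-silent"))
}

#' Dynamics class per probe for one treatment arm
#'
#' Classifies each probe by when it responds (in either direction) versus
#' Control within an arm: significant at 3 h only = `early`, at 24 h only
#' = `late`, at both = `persistent`, at neither = `silent`.
#'
#' @inheritParams select_nontrivial
#' @param arm `"HD"` (single high dose) or `"LDHD"` (primed arm).
#' @return factor (levels early, late, persistent, silent) named by probe
#'   id.
#' @export
classify_dynamics <- function(es, arm = c("HD", "LDHD"), de = de_table(es),
                              fc = 2, alpha = 0.05) {
  arm <- match.arg(arm)
  d3 <- if (arm == "HD") de$HD3 else de$LDHD3
  d24 <- if (arm == "HD") de$HD24 else de$LDHD24
  s3 <- sig_any(d3, fc, alpha); s24 <- sig_any(d24, fc, alpha)
  cls <- ifelse(s3 & s24, "persistent", ifelse(s3, "early", ifelse(s24, "late", "silent")))
  factor(stats::setNames(cls, d3$probe_id),
         levels = c("early", "late", "persistent", "silent"))
}

#' Identify candidate priming readout genes
#'
#' A relaxed readout candidate shows negligible expression change under LD
#' (class LD-silent) but higher expression under LD+HD than under HD at a
#' matching time point (fold change at least `relaxed_fc`, default 1.5,
#' mirroring the 50% excess in the priming definition). A strict candidate
#' additionally requires fold change >= `fc` with adjusted p < `alpha` on
#' the LD+HD vs HD comparison.
#'
#' @inheritParams select_nontrivial
#' @param relaxed_fc fold-change threshold of the relaxed tier (default 1.5).
#' @return data.frame with columns `probe_id`, `relaxed`, `strict`.
#' @export
identify_readouts <- function(es, de = de_table(es), fc = 2, alpha = 0.05,
                              relaxed_fc = 1.5) {
  ld_class <- classify_ld_response(es, de, fc, alpha)
  r3 <- de$LDHD3_vs_HD3; r24 <- de$LDHD24_vs_HD24
  silent <- ld_class == "LD-silent"
  relaxed <- silent & (r3$fc >= relaxed_fc | r24$fc >= relaxed_fc)
  strict <- relaxed & ((r3$fc >= fc & r3$padj < alpha) | (r24$fc >= fc & r24$padj < alpha))
  data.frame(probe_id = r3$probe_id, relaxed = relaxed, strict = strict,
             row.names = NULL)
}

#' Expression-dynamics reshuffling between the HD and primed arms
#'
#' Builds the full transition matrix of dynamics classes (early, late,
#' persistent, silent) from the single high-dose arm to the primed
#' (LD+HD) arm, plus the switched-off set (responsive under HD, silent
#' under LD+HD) and the switched-on set (silent under HD, responsive
#' under LD+HD).
#'
#' @param class_hd,class_ldhd factors from [classify_dynamics()] over the
#'   same probes.
#' @return object of class `reshuffle_result`: list with `transitions`
#'   (4x4 table, rows = HD class, columns = LD+HD class), `switched_off`,
#'   `switched_on` (probe id vectors) and `moved` (data.frame of probes
#'   that changed between two responsive classes).
#' @export
reshuffle_analysis <- function(class_hd, class_ldhd) {
  stopifnot(length(class_hd) == length(class_ldhd),
            identical(names(class_hd), names(class_ldhd)))
  lev <- c("early", "late", "persistent", "silent")
  tr <- table(factor(class_hd, lev), factor(class_ldhd, lev), dnn = c("HD", "LDHD"))
  off <- names(class_hd)[class_hd != "silent" & class_ldhd == "silent"]
  on <- names(class_hd)[class_hd == "silent" & class_ldhd != "silent"]
  moved_idx <- class_hd != "silent" & class_ldhd != "silent" &
    as.character(class_hd) != as.character(class_ldhd)
  moved <- data.frame(probe_id = names(class_hd)[moved_idx],
                      from = as.character(class_hd)[moved_idx],
                      to = as.character(class_ldhd)[moved_idx], row.names = NULL)
  structure(list(transitions = tr, switched_off = off, switched_on = on,
                 moved = moved), class = "reshuffle_result")
}

#' @export
print.reshuffle_result <- function(x, ...) {
  cat("<reshuffle_result>\n")
  print(x$transitions)
  cat("switched off:", length(x$switched_off),
      "| switched on:", length(x$switched_on),
      "| moved between responsive classes:", nrow(x$moved), "\n")
  invisible(x)
}

#' Mechanism roles per gene
#'
#' Maps the screening classes onto the roles genes can play in priming
#' motifs:
#' * `PS-regulator`: LD-induced with LD+HD expression above HD at a
#'   matched time (fold change >= `relaxed_fc` and adjusted p < `alpha`).
#' * `AI-regulator`: LD-induced with LD+HD similar to HD.
#' * `SD-suppressor`: LD-reduced.
#' * `HD-partner`: LD-silent but responsive in the HD arm (any dynamics
#'   class other than silent).
#'
#' @inheritParams identify_readouts
#' @return data.frame with columns `probe_id`, `role` (factor with the
#'   four roles plus `none`) and `ldhd_similar` (logical: LD+HD maximum
#'   indistinguishable from HD).
#' @export
assign_mechanism_roles <- function(es, de = de_table(es), fc = 2, alpha = 0.05,
                                   relaxed_fc = 1.5) {
  ld_class <- classify_ld_response(es, de, fc, alpha)
  dyn_hd <- classify_dynamics(es, "HD", de, fc, alpha)
  r3 <- de$LDHD3_vs_HD3; r24 <- de$LDHD24_vs_HD24
  excess <- (r3$fc >= relaxed_fc & r3$padj < alpha) |
    (r24$fc >= relaxed_fc & r24$padj < alpha)
  similar <- !excess
  role <- rep("none", length(ld_class))
  role[ld_class == "LD-induced" & excess] <- "PS-regulator"
  role[ld_class == "LD-induced" & similar] <- "AI-regulator"
  role[ld_class == "LD-reduced"] <- "SD-suppressor"
  role[ld_class == "LD-silent" & dyn_hd != "silent"] <- "HD-partner"
  data.frame(probe_id = names(ld_class),
             role = factor(role, levels = c("PS-regulator", "AI-regulator",
                                            "SD-suppressor", "HD-partner", "none")),
             ldhd_similar = similar, row.names = NULL)
}

#' Run the full screening pipeline
#'
#' Applies, in order: the detection-call filter, the non-trivial-dynamics
#' filter (fold change and Welch/FDR significance in at least one
#' comparison), low-dose response classes, dynamics classes in both arms,
#' readout identification, reshuffling analysis and mechanism roles.
#'
#' @param es an `expression_set`.
#' @param fc fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param relaxed_fc relaxed readout threshold (default 1.5).
#' @return object of class `priming_screen`: list with the filtered set
#'   (`es`), `de` tables, `nontrivial` ids, per-probe `classification`
#'   data.frame, `readouts`, `roles`, and `reshuffle`.
#' @export
screen_expression <- function(es, fc = 2, alpha = 0.05, relaxed_fc = 1.5) {
  es1 <- if (is.null(es$calls)) es else present_call_filter(es)
  de <- de_table(es1)
  nontrivial <- select_nontrivial(es1, de, fc, alpha)
  ld_class <- classify_ld_response(es1, de, fc, alpha)
  dyn_hd <- classify_dynamics(es1, "HD", de, fc, alpha)
  dyn_ldhd <- classify_dynamics(es1, "LDHD", de, fc, alpha)
  readouts <- identify_readouts(es1, de, fc, alpha, relaxed_fc)
  roles <- assign_mechanism_roles(es1, de, fc, alpha, relaxed_fc)
  keep <- rownames(es1$exprs) %in% nontrivial
  resh <- reshuffle_analysis(dyn_hd[keep], dyn_ldhd[keep])
  classification <- data.frame(
    probe_id = rownames(es1$exprs),
    gene_symbol = es1$probes$gene_symbol[match(rownames(es1$exprs), es1$probes$probe_id)],
    nontrivial = keep,
    ld_class = ld_class,
    dynamics_hd = dyn_hd,
    dynamics_ldhd = dyn_ldhd,
    readout_relaxed = readouts$relaxed,
    readout_strict = readouts$strict,
    role = roles$role,
    ldhd_similar = roles$ldhd_similar,
    row.names = NULL)
  structure(list(es = es1, de = de, nontrivial = nontrivial,
                 classification = classification, readouts = readouts,
                 roles = roles, reshuffle = resh,
                 thresholds = list(fc = fc, alpha = alpha, relaxed_fc = relaxed_fc)),
            class = "priming_screen")
}

#' @export
print.priming_screen <- function(x, ...) {
  cl <- x$classification
  cat("<priming_screen>", nrow(cl), "probes after detection-call filter\n")
  cat("  non-trivial dynamics:", sum(cl$nontrivial), "\n")
  cat("  LD-induced:", sum(cl$ld_class == "LD-induced"),
      "| LD-reduced:", sum(cl$ld_class == "LD-reduced"), "\n")
  cat("  readouts: relaxed", sum(cl$readout_relaxed),
      "| strict", sum(cl$readout_strict), "\n")
  invisible(x)
}

#' Role table of a screen, keyed by gene symbol
#'
#' Collapses the per-probe roles of a `priming_screen` to gene symbols for
#' use with [find_motifs()] (one row per gene-role pair, `none` dropped).
#'
#' @param screen a `priming_screen`.
#' @return data.frame with columns `gene`, `role`, `ldhd_similar`.
#' @export
roles_table <- function(screen) {
  stopifnot(inherits(screen, "priming_screen"))
  cl <- screen$classification
  keep <- cl$role != "none"
  d <- data.frame(gene = cl$gene_symbol[keep], role = as.character(cl$role[keep]),
                  ldhd_similar = cl$ldhd_similar[keep], stringsAsFactors = FALSE)
  d[!duplicated(d[, c("gene", "role")]), , drop = FALSE]
}
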