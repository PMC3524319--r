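#' Write an expression set as annotated TSV
#'
#' Tab-separated, UTF-8; sample metadata in `#`-prefixed header lines
#' (`# condition`, `# pool`) above a `probe_id` / `gene_symbol` header.
#' Detection calls, when present, are written to a companion file with the
#' same layout.
#'
#' @param es an [expression_set].
#' @param path output file for the expression matrix.
#' @param calls_path optional output file for the detection calls.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(es, path, calls_path = NULL) {
  stopifnot(inherits(es, "expression_set"))
  con <- file(path, "w")
  on.exit(close(con))
  write_block <- function(con, mat) {
    cat("# condition\t", paste(as.character(es$samples$condition), collapse = "\t"),
        "\n", sep = "", file = con)
    cat("# pool\t", paste(es$samples$pool, collapse = "\t"), "\n", sep = "", file = con)
    cat("probe_id\tgene_symbol\t", paste(colnames(mat), collapse = "\t"), "\n",
        sep = "", file = con)
    sym <- es$probes$gene_symbol[match(rownames(mat), es$probes$probe_id)]
    utils::write.table(data.frame(rownames(mat), sym, mat, check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_block(con, es$exprs)
  if (!is.null(calls_path)) {
    if (is.null(es$calls)) stop("expression set has no detection calls")
    con2 <- file(calls_path, "w")
    on.exit(close(con2), add = TRUE)
    write_block(con2, es$calls)
  }
  invisible(path)
}

parse_expr_block <- function(path, numeric_values = TRUE) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    row <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (!length(row)) stop("missing '# ", key, "' metadata line in ", path)
    strsplit(sub(paste0("^# ", key, "\t"), "", row[1]), "\t", fixed = TRUE)[[1]]
  }
  condition <- get_meta("condition")
  pool <- get_meta("pool")
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("probe_id", "gene_symbol")))
    stop("expected 'probe_id' and 'gene_symbol' as first header columns in ", path)
  sample_ids <- header[-(1:2)]
  if (length(sample_ids) != length(condition) || length(sample_ids) != length(pool))
    stop("metadata lines and sample columns disagree in length in ", path)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nfield <- length(header)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != nfield)
      stop("row ", i + 1L, " of ", path, " has ", length(rows[[i]]),
           " fields, expected ", nfield)
  }
  probe_id <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(probe_id)) {
    dup <- probe_id[duplicated(probe_id)][1]
    stop("duplicate probe id '", dup, "' in ", path)
  }
  gene_symbol <- vapply(rows, `[[`, character(1), 2L)
  cells <- t(vapply(rows, function(r) r[-(1:2)], character(nfield - 2L)))
  if (numeric_values) {
    suppressWarnings(storage.mode(cells) <- "double")
    if (anyNA(cells)) {
      bad <- which(is.na(cells), arr.ind = TRUE)[1, ]
      stop("non-numeric cell at row ", bad[1] + 1L, ", sample column ", bad[2],
           " of ", path)
    }
  }
  dimnames(cells) <- list(probe_id, sample_ids)
  list(values = cells,
       samples = data.frame(sample_id = sample_ids, condition = condition,
                            pool = as.integer(pool), stringsAsFactors = FALSE),
       probes = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE))
}

#' Read an expression set from annotated TSV
#'
#' Counterpart of [write_expression_tsv()]. Validation of condition
#' labels, probe uniqueness and numeric cells happens on load; screening
#' operations that need a missing condition raise their own errors later.
#'
#' @param path expression matrix TSV.
#' @param calls_path optional detection-call TSV with the same layout.
#' @return an [expression_set].
#' @export
read_expression_tsv <- function(path, calls_path = NULL) {
  b <- parse_expr_block(path, numeric_values = TRUE)
  calls <- NULL
  if (!is.null(calls_path)) {
    cb <- parse_expr_block(calls_path, numeric_values = FALSE)
    if (!identical(dimnames(cb$values), dimnames(b$values)))
      stop("calls file does not match the expression matrix layout")
    calls <- cb$values
  }
  expression_set(b$values, b$samples, b$probes, calls)
}

#' Write an expression set as a GDS-style SOFT subset file
#'
#' A minimal SOFT serialization (synthetic; for exercising the reader):
#' one `^SUBSET` block per condition listing its sample ids, then the
#' expression table between `!dataset_table_begin` / `!dataset_table_end`.
#'
#' @param es an [expression_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gds_soft <- function(es, path) {
  stopifnot(inherits(es, "expression_set"))
  con <- file(path, "w")
  on.exit(close(con))
  cat("^DATASET = synthetic_priming_timecourse\n", file = con)
  cat("!dataset_platform = synthetic\n", file = con)
  for (cond in levels(droplevels(es$samples$condition))) {
    ids <- es$samples$sample_id[as.character(es$samples$condition) == cond]
    cat("^SUBSET = ", cond, "\n", sep = "", file = con)
    cat("!subset_description = ", cond, "\n", sep = "", file = con)
    cat("!subset_sample_id = ", paste(ids, collapse = ","), "\n", sep = "", file = con)
  }
  cat("!dataset_table_begin\n", file = con)
  cat("ID_REF\tIDENTIFIER\t", paste(colnames(es$exprs), collapse = "\t"), "\n",
      sep = "", file = con)
  sym <- es$probes$gene_symbol[match(rownames(es$exprs), es$probes$probe_id)]
  utils::write.table(data.frame(rownames(es$exprs), sym, es$exprs,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  cat("!dataset_table_end\n", file = con)
  invisible(path)
}

#' Read a GDS-style SOFT subset file
#'
#' Convenience reader for files following the subset/table layout of GEO
#' GDS SOFT exports. Subset descriptions are mapped to the six-condition
#' scheme via `condition_map`; descriptions already using the scheme need
#' no map. Replicate pools are numbered by column order within each
#' condition. Detection calls are not part of SOFT tables.
#'
#' @param path SOFT file.
#' @param condition_map optional named character vector mapping subset
#'   descriptions to [priming_conditions()] labels.
#' @return an [expression_set].
#' @export
read_gds_soft <- function(path, condition_map = NULL) {
  lines <- readLines(path)
  desc_idx <- grep("^!subset_description", lines)
  id_idx <- grep("^!subset_sample_id", lines)
  if (length(desc_idx) != length(id_idx) || !length(desc_idx))
    stop("no subset blocks found in ", path)
  val <- function(line) trimws(sub("^[^=]*=", "", line))
  cond_of <- character(0)
  for (i in seq_along(desc_idx)) {
    desc <- val(lines[desc_idx[i]])
    cond <- if (is.null(condition_map)) desc else condition_map[[desc]]
    if (is.null(cond) || is.na(cond) || !cond %in% priming_conditions())
      stop("subset description '", desc, "' does not map to a known condition")
    ids <- trimws(strsplit(val(lines[id_idx[i]]), ",", fixed = TRUE)[[1]])
    cond_of[ids] <- cond
  }
  beg <- grep("^!dataset_table_begin", lines)
  end <- grep("^!dataset_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("malformed dataset table in ", path)
  tab <- lines[(beg + 1L):(end - 1L)]
  header <- strsplit(tab[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-(1:2)]
  missing_ids <- setdiff(sample_ids, names(cond_of))
  if (length(missing_ids))
    stop("sample(s) not covered by any subset: ", paste(missing_ids, collapse = ", "))
  rows <- strsplit(tab[-1], "\t", fixed = TRUE)
  probe_id <- vapply(rows, `[[`, character(1), 1L)
  gene_symbol <- vapply(rows, `[[`, character(1), 2L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-(1:2)]),
                   numeric(length(sample_ids))))
  dimnames(vals) <- list(probe_id, sample_ids)
  cond <- unname(cond_of[sample_ids])
  pool <- stats::ave(seq_along(cond), cond, FUN = seq_along)
  samples <- data.frame(sample_id = sample_ids, condition = cond, pool = pool,
                        stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       stringsAsFactors = FALSE)
  expression_set(vals, samples, probes)
}

# ---------------------------------------------------------------------------

run_config_defaults <- function() {
  list(
    seed = 1L,
    thresholds = list(tau_ld = 0.1, tau_hd = 0.1, rho = 0.5, delta = 0.1),
    screening = list(fc = 2, alpha = 0.05, relaxed_fc = 1.5),
    protocol = list(ld_dose = 0.1, hd_dose = 1, ld_duration = 50,
                    hd_duration = 50, wash = 0),
    metropolis = list(n_chains = 20, stage1_iters = 250, stage2_iters = 250,
                      step = 0.3, temperature = 0.05, max_records_per_chain = 2),
    motifs = list(max_len = 3)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration covering the priming thresholds, screening
#' thresholds, generic protocol timing, Metropolis settings and motif
#' matching options, fills unset fields with package defaults, and
#' rejects unknown keys with an explicit error.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return nested named list, class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping")
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (sec in names(user)) {
      if (is.list(cfg[[sec]])) {
        bad2 <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(bad2))
          stop("unknown config key(s) under '", sec, "': ",
               paste(bad2, collapse = ", "))
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  num_leaves <- unlist(cfg[c("thresholds", "screening", "protocol", "metropolis")])
  if (!all(vapply(num_leaves, is.numeric, logical(1))))
    stop("all threshold/protocol/metropolis settings must be numeric")
  structure(cfg, class = "run_config")
}

#' Serialize priming features and verdict to JSON
#'
#' @param features a [priming_features] object.
#' @param verdict optional [evaluate_priming()] result.
#' @param label optional [classify_mechanism()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_json <- function(features, path, verdict = NULL, label = NULL) {
  x <- list(readout = features$readout,
            dss_ld = as.list(features$dss_ld),
            dmax_hd = as.list(features$dmax_hd),
            dmax_ldhd = as.list(features$dmax_ldhd),
            readout_max = list(LD = features$readout_max_ld,
                               HD = features$readout_max_hd,
                               LD_HD = features$readout_max_ldhd))
  if (!is.null(verdict)) x$verdict <- list(primed = verdict$primed, reason = verdict$reason)
  if (!is.null(label)) x$mechanism <- list(label = label$label, evidence = label$evidence)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the outputs of a screening run
#'
#' Emits the per-gene classification table (TSV), the dynamics transition
#' matrix (TSV) and a JSON summary with the applied thresholds and class
#' counts.
#'
#' @param screen a `priming_screen` from [screen_expression()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_screen_results <- function(screen, dir) {
  stopifnot(inherits(screen, "priming_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(screen$classification, file.path(dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- as.data.frame.matrix(screen$reshuffle$transitions)
  utils::write.table(cbind(HD_class = rownames(tr), tr),
                     file.path(dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- screen$classification
  summary <- list(
    thresholds = screen$thresholds,
    n_probes = nrow(cl),
    n_nontrivial = sum(cl$nontrivial),
    n_ld_induced = sum(cl$ld_class == "LD-induced"),
    n_ld_reduced = sum(cl$ld_class == "LD-reduced"),
    n_readout_relaxed = sum(cl$readout_relaxed),
    n_readout_strict = sum(cl$readout_strict),
    dynamics_hd = as.list(table(cl$dynamics_hd)),
    dynamics_ldhd = as.list(table(cl$dynamics_ldhd)),
    switched_off = length(screen$reshuffle$switched_off),
    switched_on = length(screen$reshuffle$switched_on))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a motif table as TSV
#' @param motifs data.frame from [find_motifs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motifs_tsv <- function(motifs, path) {
  utils::write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
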