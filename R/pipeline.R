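# End-to-end orchestration: anchor -> distances/haplotypes/gap ->
# diagnostics -> ID-tag classification -> morphometrics -> combined
# per-specimen report, with fixed-format TSV artifacts and a MANIFEST.

#' Discover groups by single-linkage clustering of barcode distances
#'
#' Specimens are joined whenever their distance (1-decimal percent scale)
#' does not exceed the threshold. The default 1.5% is the usual ceiling of
#' Papilionini subspecies-level divergence: clusters further apart behave
#' as species-level lineages.
#'
#' @param dm a \code{barcode_dist}.
#' @param threshold_percent linkage threshold in percent (default 1.5).
#' @return named character vector specimen_id -> group id ("G1", "G2",
#'   ...); groups ordered by decreasing size, ties by lexicographically
#'   smallest member.
#' @export
cluster_groups <- function(dm, threshold_percent = 1.5) {
  ids <- dm$ids
  if (length(ids) == 1L) return(stats::setNames("G1", ids))
  hc <- stats::hclust(stats::as.dist(dm$percent), method = "single")
  raw <- stats::cutree(hc, h = threshold_percent)
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(g)
    sort(ids[raw == as.integer(g)])[1], character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(paste0("G", seq_along(ord)), names(sizes)[ord])
  stats::setNames(unname(relabel[as.character(raw)]), ids)
}

.write_tsv <- function(df, path, config_line = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(config_line)) writeLines(paste0("# ", config_line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full delimitation pipeline
#'
#' Stages, in order: read and anchor barcodes; pairwise distances (PHYLIP);
#' haplotype census; group labels (specimen taxon labels, or single-linkage
#' discovery when labels are absent); barcode-gap analysis; NJ dendrogram
#' (Newick); diagnostic-site discovery (or a supplied site table) and
#' per-specimen classification; morphometric scores and hiatus tests when
#' a measurement CSV is supplied; and a combined per-specimen report with a
#' concordance flag across evidence lines (missing lines are silent, not
#' discordant). Artifacts are written under \code{out_dir} with a MANIFEST;
#' on a stage failure the MANIFEST records the incomplete state and the
#' failing stage is named in the error.
#'
#' @param fasta path to the input FASTA.
#' @param out_dir output directory (created if needed).
#' @param morpho_csv optional morphometrics CSV
#'   (see \code{\link{read_morpho_csv}}); an empty or score-less file skips
#'   the stage with a log line.
#' @param sites optional path to a diagnostic-site TSV; default discovers
#'   sites from the labeled groups.
#' @param labels_from "auto" (taxon labels when complete, else clustering),
#'   "taxon", or "cluster".
#' @param cluster_threshold percent threshold for group discovery.
#' @param max_mismatch_fraction anchoring identity tolerance.
#' @param min_coverage diagnostic-site coverage minimum.
#' @param haplotype_min_length eligibility for the haplotype census.
#' @param verbose print stage log lines to stderr.
#' @return invisibly, a list with every stage result and the per-specimen
#'   \code{report} data frame.
#' @export
run_pipeline <- function(fasta, out_dir, morpho_csv = NULL, sites = NULL,
                         labels_from = c("auto", "taxon", "cluster"),
                         cluster_threshold = 1.5,
                         max_mismatch_fraction = 0.15, min_coverage = 2L,
                         haplotype_min_length = 658L, verbose = TRUE) {
  labels_from <- match.arg(labels_from)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_line <- sprintf(
    paste0("barcodegap %s | labels_from=%s cluster_threshold=%s ",
           "max_mismatch_fraction=%s min_coverage=%d ",
           "haplotype_min_length=%d"),
    as.character(utils::packageVersion("barcodegap")), labels_from,
    format(cluster_threshold), format(max_mismatch_fraction),
    as.integer(min_coverage), as.integer(haplotype_min_length))
  manifest <- character()
  log_msg <- function(...) if (verbose) message("[barcodegap] ", ...)
  note <- function(file) manifest <<- c(manifest, file)
  fail <- function(stage, e) {
    writeLines(c(paste0("# ", config_line), "status\tINCOMPLETE",
                 paste0("failed_stage\t", stage),
                 paste0("files\t", paste(manifest, collapse = ","))),
               file.path(out_dir, "MANIFEST"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    log_msg("stage: ", name)
    tryCatch(expr, error = function(e) fail(name, e))
  }

  records <- stage("read", read_barcode_fasta(fasta))
  aln <- stage("anchor", align_barcodes(records,
                                        max_mismatch_fraction =
                                          max_mismatch_fraction))

  dm <- stage("distances", distance_matrix(aln))
  write_phylip(dm, file.path(out_dir, "distances.phy")); note("distances.phy")

  haps <- stage("haplotypes", collapse_haplotypes(aln, haplotype_min_length))
  .write_tsv(as.data.frame(haps), file.path(out_dir, "haplotypes.tsv"),
             config_line); note("haplotypes.tsv")

  labels <- stage("labels", {
    have_taxa <- all(nzchar(records$taxon_label))
    use_taxa <- switch(labels_from, taxon = TRUE, cluster = FALSE,
                       auto = have_taxa)
    if (use_taxa && !have_taxa) stop("taxon labels are not complete")
    if (use_taxa) {
      stats::setNames(records$taxon_label, records$specimen_id)
    } else {
      cluster_groups(dm, cluster_threshold)
    }
  })

  gap <- stage("gap", barcode_gap(aln, labels, dm = dm))
  .write_tsv(data.frame(group = gap$groups,
                        max_within_percent = unname(gap$max_within),
                        min_between_percent = gap$min_between,
                        gap_points = gap$gap, verdict = gap$verdict,
                        stringsAsFactors = FALSE),
             file.path(out_dir, "barcode_gap.tsv"), config_line)
  note("barcode_gap.tsv")

  tree <- NULL
  if (nrow(aln) >= 3L) {
    tree <- stage("tree", nj_dendrogram(dm))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk")); note("tree.nwk")
  } else {
    log_msg("stage tree skipped: fewer than 3 specimens")
  }

  groups <- sort(unique(labels))
  site_table <- stage("diagnose", {
    if (!is.null(sites)) {
      read_sites_tsv(sites)
    } else {
      if (length(groups) != 2L) {
        stop("site discovery needs exactly 2 groups, got ", length(groups))
      }
      find_diagnostic_sites(aln[labels[rownames(aln)] == groups[1], ,
                                drop = FALSE],
                            aln[labels[rownames(aln)] == groups[2], ,
                                drop = FALSE], min_coverage)
    }
  })
  .write_tsv(as.data.frame(site_table),
             file.path(out_dir, "diagnostic_sites.tsv"), config_line)
  note("diagnostic_sites.tsv")

  assignments <- stage("assign", classify_alignment(aln, site_table))
  barcode_call <- stats::setNames(
    ifelse(assignments$call == "group_a", groups[1],
           ifelse(assignments$call == "group_b",
                  if (length(groups) >= 2L) groups[2] else NA_character_,
                  NA_character_)),
    assignments$specimen_id)
  .write_tsv(assignments, file.path(out_dir, "classification.tsv"),
             config_line); note("classification.tsv")

  morpho <- NULL
  hiatus <- list()
  if (!is.null(morpho_csv)) {
    morpho <- stage("morphometrics", {
      df <- tryCatch(read_morpho_csv(morpho_csv), error = function(e) NULL)
      if (is.null(df) || nrow(df) == 0L) {
        log_msg("stage morphometrics skipped: no usable measurements")
        NULL
      } else {
        if (sum(!is.na(df$true_label)) > 0 &&
            length(unique(stats::na.omit(df$true_label))) == 2L) {
          for (ax in c("g_score", "f_score")) {
            if (any(!is.na(df[[ax]]))) {
              hiatus[[ax]] <- hiatus_test(df, ax)
            }
          }
        }
        .write_tsv(df, file.path(out_dir, "morphometrics.tsv"), config_line)
        note("morphometrics.tsv")
        df
      }
    })
  }

  report <- stage("report", {
    hap_of <- stats::setNames(rep(NA_character_, nrow(records)),
                              records$specimen_id)
    for (k in seq_len(nrow(haps))) {
      for (m in strsplit(haps$members[k], ",", fixed = TRUE)[[1]]) {
        hap_of[m] <- haps$haplotype[k]
      }
    }
    pc <- dm$percent
    grp <- labels[rownames(aln)]
    nn_within <- nn_between <- rep(NA_real_, nrow(aln))
    for (i in seq_len(nrow(aln))) {
      same <- which(grp == grp[i]); same <- setdiff(same, i)
      other <- which(grp != grp[i])
      if (length(same)) nn_within[i] <- min(pc[i, same])
      if (length(other)) nn_between[i] <- min(pc[i, other])
    }
    rep_df <- data.frame(
      specimen_id = records$specimen_id,
      group = unname(labels[records$specimen_id]),
      barcode_call = unname(barcode_call[records$specimen_id]),
      votes_margin = assignments$margin[match(records$specimen_id,
                                              assignments$specimen_id)],
      haplotype = unname(hap_of),
      nn_within_percent = nn_within[match(records$specimen_id,
                                          rownames(aln))],
      nn_between_percent = nn_between[match(records$specimen_id,
                                            rownames(aln))],
      stringsAsFactors = FALSE)
    if (!is.null(morpho)) {
      mi <- match(rep_df$specimen_id, morpho$specimen_id)
      rep_df$g_score <- morpho$g_score[mi]
      rep_df$f_score <- morpho$f_score[mi]
      rep_df$morpho_call_g <- NA_character_
      rep_df$morpho_call_f <- NA_character_
      for (ax in names(hiatus)) {
        h <- hiatus[[ax]]
        call_col <- if (ax == "g_score") "morpho_call_g" else "morpho_call_f"
        sc <- rep_df[[ax]]
        rep_df[[call_col]] <- ifelse(is.na(sc), NA_character_,
                                     ifelse(sc > h$threshold,
                                            h$groups["high"],
                                            h$groups["low"]))
      }
    }
    evidence_cols <- intersect(c("barcode_call", "morpho_call_g",
                                 "morpho_call_f"), names(rep_df))
    rep_df$concordant <- apply(rep_df[, evidence_cols, drop = FALSE], 1L,
                               function(r) {
                                 r <- r[!is.na(r)]
                                 length(unique(r)) <= 1L
                               })
    rep_df
  })
  .write_tsv(report, file.path(out_dir, "specimen_report.tsv"), config_line)
  note("specimen_report.tsv")

  writeLines(c(paste0("# ", config_line), "status\tCOMPLETE",
               paste0("files\t", paste(manifest, collapse = ","))),
             file.path(out_dir, "MANIFEST"))
  invisible(list(records = records, alignment = aln, distances = dm,
                 haplotypes = haps, labels = labels, gap = gap, tree = tree,
                 sites = site_table, assignments = assignments,
                 morphometrics = morpho, hiatus = hiatus, report = report))
}
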