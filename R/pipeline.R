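# End-to-end orchestration of the pipeline stages on a synthetic cohort,
# with a checksum manifest and full determinism from one master seed.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Run the pipeline stages in dependency order
#'
#' Stages: `simulate` (synthetic cohort to disk), `segment` (per-sample
#' PMD/UMR/LMR segmentation), `specific-lmrs` (group-specific LMRs,
#' Jaccard clustering, annotation), `site-stats` (DMC/DVC and overlap),
#' `gsea` (LMR target enrichment and LMR-expression correlation), `mirna`
#' (differential miRNAs and methylation integration), `variants`
#' (candidate genes and mutation excess). Identical config and seed yield
#' byte-identical outputs; a manifest with MD5 checksums is written last.
#'
#' @param config A [cohort_config()]; its `rng_seed` drives everything.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of stages to run (default all, in order).
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c(
                           "simulate", "segment", "specific-lmrs",
                           "site-stats", "gsea", "mirna", "variants"
                         )) {
  all_stages <- c(
    "simulate", "segment", "specific-lmrs", "site-stats", "gsea",
    "mirna", "variants"
  )
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  need <- function(file, stage, prereq) {
    if (!file.exists(file)) {
      stop(
        "stage '", stage, "' requires output of stage '", prereq,
        "' (missing ", basename(file), ")"
      )
    }
  }

  state <- new.env(parent = emptyenv())

  load_samples <- function(stage) {
    if (!is.null(state$samples)) {
      return(state$samples)
    }
    sheet_f <- p("samples.tsv")
    need(sheet_f, stage, "simulate")
    sheet <- utils::read.delim(sheet_f, stringsAsFactors = FALSE)
    state$samples <- lapply(seq_len(nrow(sheet)), function(i) {
      read_bismark_coverage(
        p(paste0(sheet$sample_id[i], ".cov")),
        sheet$sample_id[i], sheet$group[i]
      )
    })
    state$groups <- stats::setNames(sheet$group, sheet$sample_id)
    state$samples
  }

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(config)
    state$samples <- sim$samples
    state$sim <- sim
    state$groups <- stats::setNames(
      sim$truth$sample_info$group, sim$truth$sample_info$sample_id
    )
    write_tsv_plain(sim$truth$sample_info, p("samples.tsv"))
    for (s in sim$samples) {
      write_bismark_coverage(s, p(paste0(s$sample_id, ".cov")))
    }
    write_bed(
      data.frame(
        chrom = "chrS", start = sim$truth$regions$start,
        end = sim$truth$regions$end,
        klass = paste(sim$truth$regions$klass,
          sim$truth$regions$group,
          sep = "_"
        )
      ),
      p("truth_regions.bed")
    )
    write_matrix_tsv(sim$expr, p("expression.tsv"))
    write_gene_models(sim$genes, p("genes.bed12"))
    write_matrix_tsv(sim$mirna_counts, p("mirna_counts.tsv"))
    write_bed(sim$mirna_genes, p("mirna_genes.bed"))
    write_tsv_plain(sim$variants, p("variants.tsv"))
    write_tsv_plain(sim$mu_table, p("mu_table.tsv"))
  }

  if ("segment" %in% stages) {
    samples <- load_samples("segment")
    state$segmentation <- lapply(samples, function(s) {
      seg <- segment_methylome(s,
        seed = derive_seed(config$rng_seed, paste0("cutoff_", s$sample_id))
      )
      write_bed(seg$all_segments, p(paste0(s$sample_id, ".segments.bed")))
      seg
    })
    names(state$segmentation) <- vapply(
      samples, `[[`, character(1), "sample_id"
    )
  }

  if ("specific-lmrs" %in% stages) {
    samples <- load_samples("specific-lmrs")
    if (is.null(state$segmentation)) {
      ids <- names(state$groups)
      for (id in ids) {
        need(p(paste0(id, ".segments.bed")), "specific-lmrs", "segment")
      }
      segs <- lapply(ids, function(id) {
        gr <- read_bed(p(paste0(id, ".segments.bed")))
        mcols(gr)$klass <- mcols(gr)$name
        gr
      })
      names(segs) <- ids
      lmrs <- segs
    } else {
      lmrs <- lapply(state$segmentation, `[[`, "segments")
    }
    spec <- call_group_specific_lmrs(lmrs, state$groups)
    state$specific <- spec
    write_bed(spec$RA, p("ra_specific_lmrs.bed"))
    write_bed(spec$OA, p("oa_specific_lmrs.bed"))
    jc <- jaccard_sample_clustering(lmrs)
    write_matrix_tsv(round(jc$jaccard, 6), p("jaccard.tsv"))
    writeLines(jc$dendrogram_newick, p("lmr_dendrogram.nwk"))
    genes_f <- p("genes.bed12")
    if (file.exists(genes_f) && length(spec$RA) > 0) {
      genes <- read_gene_models(genes_f)
      ann <- annotate_lmr_position(spec$RA, genes)
      write_tsv_plain(ann, p("ra_lmr_annotation.tsv"))
    }
  }

  if ("site-stats" %in% stages) {
    samples <- load_samples("site-stats")
    dmc <- test_dmc(samples)
    dvc <- test_dvc(samples)
    write_tsv_plain(
      within(dmc, {
        p_dmc <- signif(p_dmc, 8)
        diff <- round(diff, 6)
        mean_beta_ra <- round(mean_beta_ra, 6)
        mean_beta_oa <- round(mean_beta_oa, 6)
      }),
      p("dmc_tests.tsv")
    )
    dvc_out <- dvc
    num <- vapply(dvc_out, is.numeric, logical(1))
    dvc_out[num] <- lapply(dvc_out[num], signif, 8)
    write_tsv_plain(dvc_out, p("dvc_tests.tsv"))
    write_bed(
      data.frame(
        chrom = dmc$chrom[dmc$is_dmc], start = dmc$pos[dmc$is_dmc],
        end = dmc$pos[dmc$is_dmc] + 1, klass = dmc$direction[dmc$is_dmc]
      ),
      p("dmc.bed")
    )
    write_bed(
      data.frame(
        chrom = dvc$chrom[dvc$is_dvc], start = dvc$pos[dvc$is_dvc],
        end = dvc$pos[dvc$is_dvc] + 1, klass = dvc$direction[dvc$is_dvc]
      ),
      p("dvc.bed")
    )
    ov <- dmc_dvc_overlap_significance(
      which(dmc$is_dmc), which(dvc$is_dvc),
      universe_size = nrow(dmc),
      seed = derive_seed(config$rng_seed, "overlap")
    )
    write_tsv_plain(
      data.frame(
        n_dmc = sum(dmc$is_dmc), n_dvc = sum(dvc$is_dvc),
        n_overlap = ov$table[1, 1],
        fisher_p = signif(ov$fisher_p, 6),
        permutation_p = ov$permutation_p
      ),
      p("dmc_dvc_overlap.tsv")
    )
    state$dmc <- dmc
    state$dvc <- dvc
  }

  if ("gsea" %in% stages) {
    samples <- load_samples("gsea")
    need(p("expression.tsv"), "gsea", "simulate")
    need(p("genes.bed12"), "gsea", "simulate")
    need(p("ra_specific_lmrs.bed"), "gsea", "specific-lmrs")
    expr <- read_matrix_tsv(p("expression.tsv"))
    genes <- read_gene_models(p("genes.bed12"))
    ra_lmrs <- read_bed(p("ra_specific_lmrs.bed"))
    groups <- state$groups[colnames(expr)]
    ranking <- rank_genes_by_de(expr, groups)
    rows <- list()
    if (length(ra_lmrs) > 0) {
      gset <- build_lmr_gene_set(ra_lmrs, genes)
      if (length(intersect(gset, ranking$gene)) > 0) {
        gs <- lmr_target_gsea(ranking, gset,
          seed = derive_seed(config$rng_seed, "gsea")
        )
        rows[[1]] <- data.frame(
          set = "RA_specific_LMR_targets", n_genes = length(gset),
          es = signif(gs$es, 6), nes = signif(gs$nes, 6),
          perm_p = gs$perm_p, fdr_q = signif(gs$fdr_q, 6)
        )
      }
      nearest <- nearest_gene_by_tss(ra_lmrs, genes)
      meth <- region_methylation_matrix(ra_lmrs, samples)
      pairs <- data.frame(
        lmr = rownames(meth), gene = nearest,
        stringsAsFactors = FALSE
      )
      pairs <- pairs[pairs$gene %in% rownames(expr), , drop = FALSE]
      if (nrow(pairs) > 0) {
        cors <- correlate_lmr_expression(
          meth, expr[, names(groups), drop = FALSE], pairs,
          seed = derive_seed(config$rng_seed, "lmr_cor")
        )
        num <- vapply(cors, is.numeric, logical(1))
        cors[num] <- lapply(cors[num], signif, 6)
        write_tsv_plain(cors, p("lmr_gene_correlation.tsv"))
      }
    }
    if (length(rows) > 0) {
      write_tsv_plain(do.call(rbind, rows), p("gsea.tsv"))
    } else {
      write_tsv_plain(
        data.frame(
          set = character(), n_genes = integer(), es = numeric(),
          nes = numeric(), perm_p = numeric(), fdr_q = numeric()
        ),
        p("gsea.tsv")
      )
    }
  }

  if ("mirna" %in% stages) {
    samples <- load_samples("mirna")
    need(p("mirna_counts.tsv"), "mirna", "simulate")
    need(p("mirna_genes.bed"), "mirna", "simulate")
    counts <- read_matrix_tsv(p("mirna_counts.tsv"))
    mirna_genes <- read_bed(p("mirna_genes.bed"))
    groups <- state$groups[colnames(counts)]
    de <- test_demir(counts, groups)
    num <- vapply(de, is.numeric, logical(1))
    de_out <- de
    de_out[num] <- lapply(de_out[num], signif, 6)
    write_tsv_plain(de_out, p("demir.tsv"))
    demirs <- de$mirna[de$is_demir]
    cm <- correlate_cpg_mirna(
      samples, counts, demirs, mirna_genes,
      seed = derive_seed(config$rng_seed, "cpg_mirna")
    )
    cm$spearman_rho <- signif(cm$spearman_rho, 6)
    write_tsv_plain(cm, p("cpg_mirna_correlation.tsv"))
  }

  if ("variants" %in% stages) {
    need(p("variants.tsv"), "variants", "simulate")
    need(p("mu_table.tsv"), "variants", "simulate")
    need(p("samples.tsv"), "variants", "simulate")
    vt <- utils::read.delim(p("variants.tsv"), stringsAsFactors = FALSE)
    mu <- utils::read.delim(p("mu_table.tsv"), stringsAsFactors = FALSE)
    sheet <- utils::read.delim(p("samples.tsv"), stringsAsFactors = FALSE)
    groups <- stats::setNames(sheet$group, sheet$sample_id)
    cand <- select_candidate_genes(vt, groups)
    writeLines(cand, p("candidate_genes.txt"))
    scan <- mutation_excess_scan(vt, mu, groups)
    scan$mu <- signif(scan$mu, 6)
    scan$lambda_expected <- signif(scan$lambda_expected, 6)
    scan$p_poisson <- signif(scan$p_poisson, 6)
    write_tsv_plain(scan, p("mutation_excess.tsv"))
  }

  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), ]
  write_tsv_plain(manifest, p("manifest.tsv"))
  invisible(manifest)
}
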