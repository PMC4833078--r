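#' Build a pipeline configuration
#'
#' @param proteome_paths Named character vector: species label -> protein
#'   FASTA path.
#' @param reference_species Species playing the reference role (must be
#'   among the proteomes).
#' @param query_path Labelled query-set FASTA (reference immunity
#'   proteins with `family=` header tokens).
#' @param rules_path Family-rule YAML (see [read_family_rules()]).
#' @param anchor_refs_path FASTA of annotated anchor reference sequences.
#' @param domain_train_paths Named character vector: domain name ->
#'   training-alignment FASTA for PSSM construction.
#' @param blast_evalue,blast_identity,blast_bitscore Whole-sequence hit
#'   thresholds (strict: `evalue < 1e-6`, `identity > 0.20`,
#'   `bitscore > 80`).
#' @param pssm_margin Per-column PSSM threshold margin (see
#'   [build_pssm()]).
#' @param haplotype_identity Within-species collapse threshold.
#' @param bootstrap_replicates Bootstrap replicates for family trees.
#' @param seed RNG seed for every stochastic step (bootstrap).
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(proteome_paths, reference_species, query_path,
                            rules_path, anchor_refs_path,
                            domain_train_paths, blast_evalue = 1e-6,
                            blast_identity = 0.20, blast_bitscore = 80,
                            pssm_margin = 2, haplotype_identity = 0.99,
                            bootstrap_replicates = 100, seed = 0,
                            out_dir = tempfile("annotate_")) {
  if (!reference_species %in% names(proteome_paths)) {
    abort("reference species must be among the input proteomes")
  }
  if (blast_evalue <= 0 || blast_bitscore <= 0 || haplotype_identity <= 0) {
    abort("thresholds must be positive")
  }
  structure(list(proteome_paths = proteome_paths,
                 reference_species = reference_species,
                 query_path = query_path, rules_path = rules_path,
                 anchor_refs_path = anchor_refs_path,
                 domain_train_paths = domain_train_paths,
                 blast_evalue = blast_evalue,
                 blast_identity = blast_identity,
                 blast_bitscore = blast_bitscore,
                 pssm_margin = pssm_margin,
                 haplotype_identity = haplotype_identity,
                 bootstrap_replicates = bootstrap_replicates,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Configuration for a dataset emitted by [emit_dataset()]
#'
#' Convenience constructor pointing a [pipeline_config()] at the files of
#' an emitted synthetic dataset directory.
#'
#' @param dir Dataset directory.
#' @param ... Passed through to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_for_dataset <- function(dir, ...) {
  fastas <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  fastas <- fastas[!basename(fastas) %in%
                     c("query_set.fasta", "anchor_refs.fasta")]
  sp <- sub("\\.fasta$", "", basename(fastas))
  trains <- list.files(file.path(dir, "domains"),
                       pattern = "_train\\.fasta$", full.names = TRUE)
  names(trains) <- sub("_train\\.fasta$", "", basename(trains))
  pipeline_config(
    proteome_paths = stats::setNames(fastas, sp),
    reference_species = "refsp",
    query_path = file.path(dir, "query_set.fasta"),
    rules_path = file.path(dir, "rules.yaml"),
    anchor_refs_path = file.path(dir, "anchor_refs.fasta"),
    domain_train_paths = trains, ...)
}

stage_log <- function(log, stage, ...) {
  c(log, paste0("[", stage, "] ", paste0(..., collapse = "")))
}

#' Run the full annotation pipeline
#'
#' Stage order: read inputs, collapse within-species haplotype
#' duplicates, all-vs-all local alignment, threshold filtering,
#' reciprocal best hits and orthogroup clustering, motif and PSSM scans,
#' structural feature prediction, evidence integration, functional
#' classification, copy-number tabulation, and per-family multiple
#' alignment with a midpoint-rooted bootstrapped neighbor-joining tree.
#' Every stage's outputs are written under `config$out_dir`; the run log
#' records thresholds, the seed and per-stage record counts. Output is
#' byte-deterministic given an identical configuration and seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list of class `annotation_run` with `annotation`,
#'   `rejected`, `copy_number`, `orthogroups`, `rbh`, `structure`,
#'   `domain_hits`, `motif_hits`, `collapse_report`, `trees` (named list
#'   of `phylo`), `log` and `out_dir`.
#' @export
run_annotate <- function(config) {
  set.seed(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  log <- character(0)
  log <- stage_log(log, "config",
                   "seed=", config$seed,
                   " evalue<", config$blast_evalue,
                   " identity>", config$blast_identity,
                   " bitscore>", config$blast_bitscore,
                   " haplotype>=", config$haplotype_identity)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # 1. read
  proteins <- run_stage("read", {
    sp_order <- sort(names(config$proteome_paths))
    bind_rows(lapply(sp_order, function(sp) {
      read_fasta(config$proteome_paths[[sp]], species = sp)
    }))
  })
  queries <- run_stage("read", {
    q <- read_fasta(config$query_path, species = config$reference_species)
    if (any(is.na(q$family))) {
      abort("query set contains records without a family= label")
    }
    q
  })
  anchor_refs <- run_stage("read",
                           read_fasta(config$anchor_refs_path,
                                      species = "reference"))
  rules <- run_stage("read", read_family_rules(config$rules_path))
  log <- stage_log(log, "read", nrow(proteins), " proteins, ",
                   nrow(queries), " queries, ", nrow(rules$rules),
                   " family rules")

  # 2. collapse haplotype duplicates per species
  collapsed <- run_stage("collapse_haplotypes", {
    per_sp <- lapply(split(proteins, proteins$species), collapse_haplotypes,
                     identity_threshold = config$haplotype_identity)
    list(proteins = bind_rows(lapply(per_sp, `[[`, "proteins")),
         report = bind_rows(lapply(per_sp, `[[`, "report")))
  })
  proteins <- collapsed$proteins %>%
    arrange(.data$species, .data$protein_id)
  log <- stage_log(log, "collapse_haplotypes", nrow(collapsed$report),
                   " merges, ", nrow(proteins), " proteins retained")

  # 3-4. all-vs-all alignment + threshold filter
  hits <- run_stage("align", all_vs_all_hits(proteins))
  filtered <- run_stage("filter", filter_hits_blast(hits))
  log <- stage_log(log, "align", nrow(hits), " hits, ", nrow(filtered),
                   " past thresholds")

  # 5. reciprocal best hits + orthogroups
  rbh <- run_stage("rbh",
                   best_reciprocal_hits(filtered,
                                        config$reference_species))
  orthogroups <- run_stage("orthogroups",
                           cluster_orthogroups(filtered, proteins, queries))
  log <- stage_log(log, "rbh", nrow(rbh), " reciprocal pairs")
  log <- stage_log(log, "orthogroups",
                   length(unique(orthogroups$group_id)), " groups, ",
                   sum(!is.na(orthogroups$family) & !duplicated(
                     orthogroups$group_id)), " family-labelled")

  # 6. motif + PSSM scans
  motif_hits <- run_stage("motifscan", {
    bind_rows(lapply(names(rules$motifs), function(mid) {
      scan_motif(proteins, compile_degenerate_motif(rules$motifs[[mid]],
                                                    mid))
    }))
  })
  pssms <- run_stage("pssm", {
    lapply(stats::setNames(nm = sort(names(config$domain_train_paths))),
           function(dn) {
             build_pssm(read_msa(config$domain_train_paths[[dn]]),
                        margin = config$pssm_margin, domain = dn)
           })
  })
  domain_hits <- run_stage("pssm", {
    dh <- bind_rows(lapply(pssms, function(p) scan_pssm(proteins, p)))
    if (nrow(dh) == 0) {
      dh <- tibble(domain = character(0), start = integer(0),
                   end = integer(0), score = numeric(0),
                   species = character(0), protein_id = character(0))
    }
    dh
  })
  log <- stage_log(log, "motifscan", nrow(motif_hits), " motif hits")
  log <- stage_log(log, "pssm", nrow(domain_hits), " domain hits from ",
                   length(pssms), " models")

  # 7. structural features
  structure_tbl <- run_stage("features", predict_structure(proteins))
  log <- stage_log(log, "features",
                   sum(structure_tbl$signal_peptide), " signal peptides, ",
                   sum(structure_tbl$n_tm > 0), " TM proteins")

  # 8. evidence integration
  integrated <- run_stage("integrate", {
    integrate_evidence(proteins, rules, rbh, orthogroups, domain_hits,
                       motif_hits, structure_tbl, queries,
                       known_domains = names(pssms))
  })
  annotation <- integrated$accepted
  log <- stage_log(log, "integrate", nrow(annotation), " accepted, ",
                   nrow(integrated$rejected), " rejected")

  # 9. functional classification
  annotation <- run_stage("classify", {
    classify_functional(annotation, proteins, rules, anchor_refs,
                        domain_hits, structure_tbl)
  })

  # 10. copy numbers
  copy_number <- run_stage("copy_number", {
    copy_number_matrix(annotation,
                       species = sort(names(config$proteome_paths)),
                       families = rules$rules$family)
  })

  # 11. per-family alignment + tree
  trees <- run_stage("trees", {
    trees <- list()
    for (fam in rules$rules$family) {
      members <- annotation[annotation$family == fam, ]
      if (nrow(members) < 3) next
      key <- paste0(members$species, "|", members$protein_id)
      seqs <- proteins$sequence[match(key, paste0(proteins$species, "|",
                                                  proteins$protein_id))]
      msa <- progressive_msa(tibble(protein_id = key, sequence = seqs))
      if (nrow(members) >= 4) {
        phy <- bootstrap_support(msa, config$bootstrap_replicates,
                                 seed = config$seed)
      } else {
        # a 3-taxon tree has no internal bipartition to support
        phy <- neighbor_joining(msa_distances(msa, "poisson"))
      }
      phy <- midpoint_root(phy)
      trees[[fam]] <- phy
      write_msa(msa, file.path(out_dir, "trees", paste0(fam, ".afa")))
      write_newick(phy, file.path(out_dir, "trees", paste0(fam, ".nwk")))
    }
    trees
  })
  log <- stage_log(log, "trees", length(trees), " family trees (",
                   config$bootstrap_replicates, " bootstrap replicates)")

  # 12. write outputs
  write_annotation_table(annotation, file.path(out_dir, "annotation.tsv"))
  write_copy_number_matrix(copy_number,
                           file.path(out_dir, "copy_number.tsv"))
  write_hit_table(filtered, file.path(out_dir, "filtered_hits.tsv"))
  readr::write_tsv(rbh, file.path(out_dir, "rbh.tsv"), progress = FALSE)
  readr::write_tsv(orthogroups, file.path(out_dir, "orthogroups.tsv"),
                   progress = FALSE)
  readr::write_tsv(collapsed$report,
                   file.path(out_dir, "collapse_report.tsv"),
                   progress = FALSE)
  readr::write_tsv(integrated$rejected, file.path(out_dir, "rejected.tsv"),
                   progress = FALSE)
  struct_flat <- structure_tbl %>%
    select("species", "protein_id", "signal_peptide", "localization",
           "n_tm", "n_lrr", "n_cys_clusters")
  readr::write_tsv(struct_flat, file.path(out_dir, "structure.tsv"),
                   progress = FALSE)
  if (nrow(domain_hits)) {
    write_domain_hits(domain_hits[order(domain_hits$species,
                                        domain_hits$protein_id,
                                        domain_hits$start), ],
                      file.path(out_dir, "domain_hits.tsv"))
  }
  writeLines(log, file.path(out_dir, "log.txt"))

  invisible(structure(
    list(annotation = annotation, rejected = integrated$rejected,
         copy_number = copy_number, orthogroups = orthogroups, rbh = rbh,
         structure = structure_tbl, domain_hits = domain_hits,
         motif_hits = motif_hits, collapse_report = collapsed$report,
         trees = trees, log = log, out_dir = out_dir),
    class = "annotation_run"))
}

# attach functional key=value calls to accepted records, per the family's
# configured classifier
classify_functional <- function(annotation, proteins, rules, anchor_refs,
                                domain_hits, structure_tbl) {
  if (nrow(annotation) == 0) return(annotation)
  pkey <- paste0(proteins$species, "|", proteins$protein_id)
  seq_of <- stats::setNames(proteins$sequence, pkey)
  for (j in seq_len(nrow(rules$rules))) {
    r <- rules$rules[j, ]
    rows <- which(annotation$family == r$family)
    if (length(rows) == 0) next
    akey <- paste0(annotation$species[rows], "|",
                   annotation$protein_id[rows])
    if (r$classifier == "anchored" && length(r$residue_anchors[[1]])) {
      anchor <- rules$anchors[rules$anchors$anchor_id ==
                                r$residue_anchors[[1]][1], ]
      ref_seq <- anchor_refs$sequence[anchor_refs$protein_id ==
                                        anchor$reference_id]
      if (length(ref_seq) != 1) {
        abort(paste0("anchor reference ", anchor$reference_id,
                     " not found"))
      }
      msa <- progressive_msa(tibble(
        protein_id = c(anchor$reference_id, akey),
        sequence = c(ref_seq, unname(seq_of[akey]))))
      for (i in seq_along(rows)) {
        call <- anchored_call(msa, akey[i], anchor, r$family)
        annotation$functional[[rows[i]]] <- c(
          annotation$functional[[rows[i]]],
          catalytic = if (call$state == "catalytic") "yes" else "no",
          anchor_residues = paste(call$states$observed, collapse = ""))
      }
    }
    if (r$classifier == "tep") {
      for (i in seq_along(rows)) {
        tc <- tep_classify(seq_of[[akey[i]]])
        annotation$functional[[rows[i]]] <- c(
          annotation$functional[[rows[i]]],
          tep_class = tc$class,
          thioester = if (tc$thioester_motif_present) "present" else
            "absent",
          critical_cys = if (tc$critical_cys_present) "yes" else "no")
      }
    }
    if (r$classifier == "tlr") {
      for (i in seq_along(rows)) {
        st <- structure_tbl[paste0(structure_tbl$species, "|",
                                   structure_tbl$protein_id) == akey[i], ]
        tir <- any(domain_hits$domain == "TIR" &
                     paste0(domain_hits$species, "|",
                            domain_hits$protein_id) == akey[i])
        tc <- classify_tlr(st, tir,
                           seq_length = nchar(seq_of[[akey[i]]]))
        annotation$functional[[rows[i]]] <- c(
          annotation$functional[[rows[i]]],
          tlr_class = tc$class,
          n_cys_clusters = as.character(tc$n_clusters),
          truncated = if (tc$truncated) "yes" else "no")
      }
    }
    if (r$classifier == "relish") {
      for (i in seq_along(rows)) {
        dh <- domain_hits[paste0(domain_hits$species, "|",
                                 domain_hits$protein_id) == akey[i], ]
        ra <- relish_architecture(dh)
        annotation$functional[[rows[i]]] <- c(
          annotation$functional[[rows[i]]],
          rhd = if (ra$has_rhd) "yes" else "no",
          ankyrin = if (ra$has_ankyrin_region) "yes" else "no")
      }
    }
    for (mid in r$report_motifs[[1]]) {
      pat <- rules$motifs[[mid]]
      for (i in seq_along(rows)) {
        h <- scan_motif(seq_of[[akey[i]]],
                        compile_degenerate_motif(pat, mid))
        annotation$functional[[rows[i]]] <- c(
          annotation$functional[[rows[i]]],
          stats::setNames(if (nrow(h) > 0) "yes" else "no",
                          tolower(mid)))
      }
    }
  }
  annotation
}

#' Emit a synthetic dataset (simulation entry point)
#'
#' Thin wrapper over [emit_dataset()] matching the pipeline interface.
#'
#' @param config A `generator_config`.
#' @param dir Output directory.
#' @return Invisibly, the [emit_dataset()] result.
#' @export
run_simulate <- function(config = default_generator_config(), dir) {
  emit_dataset(config, dir)
}

#' Verify an annotation against a generator truth table
#'
#' Computes per-family and overall precision/recall of family assignment
#' (background proteins count as false positives when annotated) and the
#' agreement of every functional call present in both the annotation and
#' the truth (localization, catalytic state, thioester class, receptor
#' cysteine-cluster class, RHIM presence), measured over correctly
#' assigned proteins.
#'
#' @param annotation Accepted annotation tibble (or path to a TSV written
#'   by [write_annotation_table()]).
#' @param truth Truth tibble (or path to an emitted `truth.tsv`).
#' @return List with `family_metrics` (tibble: family, tp, fp, fn,
#'   precision, recall), `overall` (one-row tibble), `functional`
#'   (tibble: key, n, agreement).
#' @export
verify_annotation <- function(annotation, truth) {
  if (is.character(annotation)) annotation <- read_annotation_table(annotation)
  if (is.character(truth)) {
    truth <- readr::read_tsv(truth, col_types = readr::cols(
      .default = "c"), progress = FALSE)
  }
  tkey <- paste0(truth$species, "|", truth$protein_id)
  akey <- paste0(annotation$species, "|", annotation$protein_id)
  truth_fam <- stats::setNames(truth$family, tkey)
  fams <- sort(unique(c(annotation$family,
                        setdiff(truth$family, "background"))))
  fam_rows <- lapply(fams, function(f) {
    pred <- akey[annotation$family == f]
    act <- tkey[truth$family == f]
    tp <- sum(pred %in% act)
    fp <- length(pred) - tp
    fn <- length(act) - tp
    tibble(family = f, tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  fam_tbl <- bind_rows(fam_rows)
  tp <- sum(fam_tbl$tp); fp <- sum(fam_tbl$fp); fn <- sum(fam_tbl$fn)
  overall <- tibble(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  # functional agreement over correctly assigned proteins
  correct <- annotation[truth_fam[akey] == annotation$family &
                          !is.na(truth_fam[akey]), ]
  ckey <- paste0(correct$species, "|", correct$protein_id)
  tix <- match(ckey, tkey)
  keymap <- list(localization = "localization", catalytic = "catalytic",
                 tep_class = "tep_class", tlr_class = "tlr_class",
                 rhim = "rhim")
  func_rows <- lapply(names(keymap), function(kk) {
    tv <- truth[[keymap[[kk]]]][tix]
    av <- vapply(correct$functional, function(f) {
      if (kk %in% names(f)) unname(f[[kk]]) else NA_character_
    }, character(1))
    use <- !is.na(tv)
    n <- sum(use)
    if (n == 0) return(NULL)
    tibble(key = kk, n = n,
           agreement = mean(!is.na(av[use]) & av[use] == tv[use]))
  })
  list(family_metrics = fam_tbl, overall = overall,
       functional = bind_rows(func_rows))
}
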