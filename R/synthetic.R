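# Hydrophilic sampling set used where a construct must not look like a
# signal peptide or TM helix by accident.
AA_HYDROPHILIC <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P")
AA_NO_CYS <- setdiff(AA20, "C")

sample_aa <- function(n, letters = AA20, prob = NULL) {
  if (is.null(prob)) prob <- AA_BACKGROUND[letters] / sum(AA_BACKGROUND[letters])
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

#' Substitute residues at a fixed per-site rate
#'
#' Each unprotected position is substituted with probability `rate`; the
#' replacement is drawn uniformly from the 19 other canonical letters.
#' Protected positions (functional anchors, planted motifs and structural
#' elements) are never touched.
#'
#' @param sequence Amino-acid string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Optional RNG seed (otherwise the current RNG stream is
#'   used).
#' @param protected Integer vector of 1-based positions to leave
#'   untouched.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL,
                            protected = integer(0)) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  free <- setdiff(seq_along(chars), protected)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Number of lineage copies surviving a birth-death process of duration t
# (linear birth-death, one ancestral copy).
simulate_bd_lineage <- function(t, birth, death) {
  if (birth == 0 && death == 0) return(1L)
  total <- birth + death
  wait <- stats::rexp(1, total)
  if (wait >= t) return(1L)
  if (stats::runif(1) < birth / total) {
    simulate_bd_lineage(t - wait, birth, death) +
      simulate_bd_lineage(t - wait, birth, death)
  } else {
    0L
  }
}

#' Evolve gene-family copy numbers along a species tree
#'
#' Runs a linear birth-death process (duplication and loss as exponential
#' waiting-time events at the given per-unit-branch-length rates)
#' independently for each ancestral copy along every branch of the species
#' tree. Surviving lineages at each tip become that species' gene copies.
#'
#' @param species_tree A `phylo` tree or Newick string with branch lengths
#'   in substitutions/site.
#' @param n_ancestral Ancestral copy number at the root.
#' @param birth,death Duplication and loss rates per unit branch length.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per surviving tip copy: `species`,
#'   `ancestral_copy` (1-based index of the root copy), `lineage` (a
#'   stable label recording the duplication history, e.g. `a1.2.1`).
#' @export
evolve_family <- function(species_tree, n_ancestral, birth = 0, death = 0,
                          seed = NULL) {
  if (birth < 0 || death < 0) abort("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- if (is.character(species_tree)) ape::read.tree(text = species_tree)
  else species_tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- list()
  descend <- function(node, lineages) {
    if (node <= ntip) {
      if (length(lineages)) {
        out[[length(out) + 1]] <<- tibble(
          species = tree$tip.label[node],
          ancestral_copy = vapply(lineages, function(l) l$anc, integer(1)),
          lineage = vapply(lineages, function(l) l$label, character(1)))
      }
      return(invisible())
    }
    kids <- which(tree$edge[, 1] == node)
    for (e in kids) {
      child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      nxt <- list()
      for (l in lineages) {
        k <- simulate_bd_lineage(len, birth, death)
        if (k == 1) {
          nxt[[length(nxt) + 1]] <- l
        } else if (k > 1) {
          for (d in seq_len(k)) {
            nxt[[length(nxt) + 1]] <- list(
              anc = l$anc, label = paste0(l$label, ".", d))
          }
        }
      }
      descend(child, nxt)
    }
  }
  start <- lapply(seq_len(n_ancestral), function(i) {
    list(anc = i, label = paste0("a", i))
  })
  descend(root, start)
  if (length(out) == 0) {
    return(tibble(species = character(0), ancestral_copy = integer(0),
                  lineage = character(0)))
  }
  bind_rows(out)
}

# ---- protein grammar ----------------------------------------------------

# An element is list(seq, protected (relative), features = tibble(feature,
# start, end)). assemble_elements() concatenates and shifts coordinates.
el <- function(seq, protected = integer(0), feature = NULL) {
  feats <- if (is.null(feature)) {
    tibble(feature = character(0), start = integer(0), end = integer(0))
  } else {
    tibble(feature = feature, start = 1L, end = nchar(seq))
  }
  list(seq = seq, protected = protected, features = feats)
}

el_signal <- function() {
  core <- paste(sample(c("L", "I", "V", "F", "A"), 12, replace = TRUE,
                       prob = c(0.45, 0.2, 0.2, 0.1, 0.05)), collapse = "")
  seq <- paste0("MK", sample_aa(2, AA_HYDROPHILIC), core, "AQA")
  x <- el(seq, protected = 5:16, feature = "SIGNAL")
  x
}

el_linker <- function(n, letters = AA_NO_CYS) el(sample_aa(n, letters))

el_domain <- function(name, consensus, extra_protected = integer(0)) {
  el(consensus, protected = extra_protected, feature = name)
}

el_motif_instance <- function(name, pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  chars[chars == "X"] <- sample(AA_NO_CYS, sum(chars == "X"),
                                replace = TRUE)
  el(paste(chars, collapse = ""), protected = seq_along(chars),
     feature = name)
}

el_lrr_unit <- function(l_class = LRR_L_CLASS) {
  n_class_safe <- c("N", "T", "S")
  unit <- sample_aa(11, AA_NO_CYS)
  chars <- strsplit(unit, "", fixed = TRUE)[[1]]
  chars[c(1, 4, 6, 11)] <- sample(l_class, 4, replace = TRUE)
  chars[9] <- sample(n_class_safe, 1)
  el(paste(chars, collapse = ""), protected = c(1L, 4L, 6L, 9L, 11L),
     feature = "LRR")
}

el_cys_cluster <- function() {
  mid <- sample_aa(2, AA_NO_CYS)
  el(paste0("C", mid, "C"), protected = 1:4, feature = "CYS_CLUSTER")
}

el_tm <- function() {
  seq <- paste(sample(c("L", "I", "V", "F"), 23, replace = TRUE,
                      prob = c(0.5, 0.25, 0.2, 0.05)), collapse = "")
  el(seq, protected = 1:23, feature = "TM")
}

assemble_elements <- function(elements) {
  seqs <- vapply(elements, function(e) e$seq, character(1))
  offsets <- c(0L, cumsum(nchar(seqs)))[seq_along(seqs)]
  feats <- purrr::map2_dfr(elements, offsets, function(e, off) {
    f <- e$features
    f$start <- f$start + off; f$end <- f$end + off
    f
  })
  protected <- unlist(purrr::map2(elements, offsets, function(e, off) {
    e$protected + off
  }))
  list(sequence = paste(seqs, collapse = ""),
       features = feats, protected = as.integer(protected))
}

# Generate the per-dataset domain consensus sequences. The first 30
# residues of each domain are hydrophilic so a domain at a protein's
# N-terminus cannot mimic a signal peptide.
generate_domain_consensus <- function() {
  lens <- c(PGRP = 160L, GH16 = 220L, TEP = 180L, TIR = 140L, RHD = 150L,
            ANK = 33L)
  doms <- lapply(lens, function(L) {
    head_len <- min(30L, L)
    paste0(sample_aa(head_len, AA_HYDROPHILIC),
           sample_aa(L - head_len))
  })
  # impose functional anchor residues
  doms$PGRP <- impose(doms$PGRP, c(40, 57, 65), c("C", "H", "H"))
  doms$GH16 <- impose(doms$GH16, c(158, 163), c("E", "E"))
  doms
}

impose <- function(seq, pos, letters) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- letters
  paste(chars, collapse = "")
}

# anchor positions inside the domain consensus, 1-based
PGRP_TRIAD_DOMAIN_POS <- c(40L, 57L, 65L)
GH16_GLU_DOMAIN_POS <- c(158L, 163L)
NIM_PATTERN <- "CXPXCXXXCXNGXCXXPXXCXCXXGY"

#' Build one synthetic protein from a family grammar
#'
#' Assembles a family-specific arrangement of signal peptide, linkers,
#' domain blocks, motifs, LRR repeats, cysteine clusters and transmembrane
#' helix, recording every planted feature's coordinates and the set of
#' positions that must be protected from substitution. Random linker and
#' spacer residues are cysteine-free so the planted cysteine clusters are
#' the only ones in an ectodomain.
#'
#' @param family One of `PGRP`, `GH16`, `TEP`, `TLR`, `Relish`, `Nimrod`.
#' @param domains Named list of domain consensus sequences (see the
#'   generator configuration).
#' @param opts List of family options: `signal` (PGRP), `tlr_class`
#'   (`"scc"`/`"mcc"`), `truncated` (Relish), `rhim` (PGRP).
#' @param seed Optional RNG seed.
#' @return List with `sequence`, `features` (tibble `feature`, `start`,
#'   `end`), `protected` (integer positions), `truth` (named list of
#'   functional truths fixed by construction).
#' @export
build_protein <- function(family, domains, opts = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- list()
  els <- switch(
    family,
    PGRP = {
      truth$localization <- if (isTRUE(opts$signal)) "secreted" else
        "intracellular"
      e <- list()
      if (isTRUE(opts$signal)) e <- c(e, list(el_signal()))
      # leading linker hydrophilic when there is no signal, so an
      # intracellular copy cannot mimic a signal core by chance
      e <- c(e, list(if (isTRUE(opts$signal)) el_linker(15) else
        el_linker(15, AA_HYDROPHILIC),
                     el_domain("PGRP", domains$PGRP,
                               extra_protected = PGRP_TRIAD_DOMAIN_POS),
                     el_linker(20)))
      if (isTRUE(opts$rhim)) {
        e <- c(e, list(el_motif_instance("RHIM", rhim_consensus()),
                       el_linker(10)))
      }
      e
    },
    GH16 = {
      truth$localization <- "secreted"
      list(el_signal(), el_linker(12),
           el_domain("GH16", domains$GH16,
                     extra_protected = GH16_GLU_DOMAIN_POS),
           el_linker(25))
    },
    TEP = {
      truth$localization <- "secreted"
      list(el_signal(), el_linker(40),
           el_domain("TEP", domains$TEP),
           el_linker(12),  # C-free flank ahead of the thioester site
           el_motif_instance("GCGEQ_site", "GCGEQ"),
           el_linker(12),  # C-free flank behind
           el_linker(60))
    },
    TLR = {
      truth$localization <- "transmembrane"
      truth$tlr_class <- opts$tlr_class %||% "mcc"
      n_rep <- 12L
      reps <- list()
      for (r in seq_len(n_rep)) {
        reps <- c(reps, list(el_lrr_unit(), el_linker(13)))
        if (truth$tlr_class == "mcc" && r == 4L) {
          reps <- c(reps, list(el_cys_cluster(), el_linker(13)))
        }
      }
      c(list(el_signal(), el_linker(20)), reps,
        list(el_cys_cluster(),        # juxtamembrane cluster
             el_linker(8), el_tm(), el_linker(10),
             el_domain("TIR", domains$TIR), el_linker(15)))
    },
    Relish = {
      truth$localization <- "intracellular"
      truth$relish_truncated <- isTRUE(opts$truncated)
      e <- list(el_domain("RHD", domains$RHD), el_linker(20))
      if (!isTRUE(opts$truncated)) {
        for (k in 1:4) e <- c(e, list(el_domain("ANK", domains$ANK)))
      }
      c(e, list(el_linker(20)))
    },
    Nimrod = {
      truth$localization <- "secreted"
      e <- list(el_signal(), el_linker(20))
      for (k in 1:3) {
        e <- c(e, list(el_motif_instance("NIM", NIM_PATTERN),
                       el_linker(10)))
      }
      c(e, list(el_linker(120)))
    },
    abort(paste0("unknown family grammar: ", family)))
  res <- assemble_elements(els)
  res$truth <- truth
  res
}

# full-sequence anchor positions of a built protein
anchor_positions <- function(built, family) {
  feats <- built$features
  if (family == "PGRP") {
    d <- feats[feats$feature == "PGRP", ][1, ]
    d$start + PGRP_TRIAD_DOMAIN_POS - 1L
  } else if (family == "GH16") {
    d <- feats[feats$feature == "GH16", ][1, ]
    d$start + GH16_GLU_DOMAIN_POS - 1L
  } else {
    integer(0)
  }
}

#' Default generator configuration
#'
#' Four species related by a balanced tree (`refsp` plays the reference
#' role), six immune families (PGRP, GH16, TEP, TLR, Relish, Nimrod) with
#' small ancestral copy numbers, and 200 background proteins per species.
#' `divergence` sets the species-tree branch lengths (substitutions/site);
#' the standard recoverable setting is 0.05, the stress setting 0.4.
#' Setting `divergence`, `birth` and `death` all to zero gives the
#' noise-free dataset on which recovery is exact by construction.
#'
#' @param divergence Branch length of each terminal branch (internal
#'   branches get half).
#' @param birth,death Duplication/loss rates per unit branch length.
#' @param n_background Background proteins per species.
#' @param seed RNG seed.
#' @return A `generator_config` list.
#' @export
default_generator_config <- function(divergence = 0.05, birth = 0.3,
                                     death = 0.15, n_background = 200,
                                     seed = 0) {
  d <- divergence; h <- divergence / 2
  tree <- sprintf("((sp1:%g,sp2:%g):%g,(sp3:%g,refsp:%g):%g);",
                  d, d, h, d, d, h)
  fams <- list(
    PGRP = list(n_ancestral = 3L, ablation_prob = 0.4,
                signal_prob = 0.5, rhim_prob = 0.4),
    GH16 = list(n_ancestral = 2L, ablation_prob = 0.4),
    TEP = list(n_ancestral = 2L, ablation_prob = 0.4),
    TLR = list(n_ancestral = 2L, scc_prob = 0.5),
    Relish = list(n_ancestral = 1L, truncation_prob = 0.3),
    Nimrod = list(n_ancestral = 2L))
  structure(list(species_tree = tree, reference_species = "refsp",
                 families = fams, birth = birth, death = death,
                 n_background = n_background,
                 background_length = c(shape = 6, scale = 55),
                 seed = seed),
            class = "generator_config")
}

apply_ablation <- function(seq, positions, expected) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (k in seq_along(positions)) {
    bad <- setdiff(AA20, c(expected[k], "C"))
    chars[positions[k]] <- sample(bad, 1)
  }
  paste(chars, collapse = "")
}

#' Emit a complete synthetic dataset with ground truth
#'
#' Generates multi-species proteomes by building one ancestral template
#' per (family, ancestral copy), evolving copy numbers by birth-death
#' along the species tree and sequences by per-branch substitution
#' (diagnostic features protected), then planting per-copy functional
#' variation: anchor-residue ablation (PGRP triad, GH16 glutamates),
#' thioester-motif ablation (TEP), scc/mcc receptor architecture (TLR,
#' per ancestral copy), ankyrin truncation (Relish) and RHIM presence
#' (PGRP, per ancestral copy). Background proteins carry no planted
#' features.
#'
#' Writes, under `dir`: one `<species>.fasta` per species, a labelled
#' `query_set.fasta` (the reference species' family proteins),
#' `rules.yaml` (family rules, anchors, motifs), `anchor_refs.fasta`
#' (annotated anchor references), `domains/<name>_train.fasta` (PSSM
#' training alignments), `truth.tsv`, `truth_features.tsv`,
#' `genealogy.tsv` and `species_tree.nwk`. Output is byte-deterministic
#' given the seed.
#'
#' @param config A `generator_config` (see [default_generator_config()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `proteins`, `truth`, `features`,
#'   `rules_path`, `dir` and the per-file paths.
#' @export
emit_dataset <- function(config, dir) {
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "domains"), showWarnings = FALSE)
  tree <- ape::read.tree(text = config$species_tree)
  species <- sort(tree$tip.label)
  refsp <- config$reference_species
  doms <- generate_domain_consensus()

  proteins <- list(); truth <- list(); feats_out <- list()
  genealogy <- list()

  for (fam in names(config$families)) {
    spec <- config$families[[fam]]
    for (anc in seq_len(spec$n_ancestral)) {
      opts <- list()
      if (fam == "PGRP") {
        opts$signal <- stats::runif(1) < (spec$signal_prob %||% 0.5)
        opts$rhim <- stats::runif(1) < (spec$rhim_prob %||% 0)
      }
      if (fam == "TLR") {
        opts$tlr_class <- if (stats::runif(1) < (spec$scc_prob %||% 0.5))
          "scc" else "mcc"
      }
      if (fam == "Relish") {
        opts$truncated <- stats::runif(1) < (spec$truncation_prob %||% 0)
      }
      template <- build_protein(fam, doms, opts)
      tips <- evolve_copies_along_tree(tree, template$sequence,
                                       template$protected,
                                       config$birth, config$death)
      counter <- stats::setNames(rep(0L, length(species)), species)
      for (r in seq_len(nrow(tips))) {
        sp <- tips$species[r]
        counter[sp] <- counter[sp] + 1L
        pid <- paste0(sp, "_", fam, "_a", anc,
                      if (counter[sp] > 1) paste0("d", counter[sp]) else "")
        seqr <- tips$sequence[r]
        tr <- template$truth
        tr$catalytic <- NA
        tr$tep_class <- NA_character_
        if (fam %in% c("PGRP", "GH16")) {
          pos <- anchor_positions(template, fam)
          expected <- if (fam == "PGRP") c("C", "H", "H") else c("E", "E")
          ablated <- stats::runif(1) < (spec$ablation_prob %||% 0)
          if (ablated) seqr <- apply_ablation(seqr, pos, expected)
          tr$catalytic <- if (ablated) "no" else "yes"
        }
        if (fam == "TEP") {
          site <- template$features[
            template$features$feature == "GCGEQ_site", ][1, ]
          ablated <- stats::runif(1) < (spec$ablation_prob %||% 0)
          if (ablated) {
            seqr <- impose(seqr, site$start + 1L, "A")  # GCGEQ -> GAGEQ
          }
          tr$tep_class <- if (ablated) "MCR-like" else "TEP"
        }
        if (fam == "PGRP") tr$rhim <- if (isTRUE(opts$rhim)) "yes" else "no"
        proteins[[length(proteins) + 1]] <- tibble(
          species = sp, protein_id = pid, sequence = seqr, family = fam)
        truth[[length(truth) + 1]] <- tibble(
          species = sp, protein_id = pid, family = fam,
          orthogroup = paste0(fam, "_a", anc),
          localization = tr$localization,
          catalytic = as.character(tr$catalytic),
          tep_class = tr$tep_class,
          tlr_class = tr$tlr_class %||% NA_character_,
          rhim = tr$rhim %||% NA_character_,
          relish_truncated = as.character(tr$relish_truncated %||% NA))
        f <- template$features
        f$species <- sp; f$protein_id <- pid
        feats_out[[length(feats_out) + 1]] <- f
        genealogy[[length(genealogy) + 1]] <- tibble(
          species = sp, protein_id = pid, family = fam,
          ancestral_copy = anc, lineage = tips$lineage[r])
      }
    }
  }

  # background proteins (no planted features)
  bl <- config$background_length
  for (sp in species) {
    n <- config$n_background
    lens <- pmin(pmax(round(stats::rgamma(n, shape = bl["shape"],
                                          scale = bl["scale"])), 80), 1200)
    for (i in seq_len(n)) {
      pid <- sprintf("%s_bg%03d", sp, i)
      proteins[[length(proteins) + 1]] <- tibble(
        species = sp, protein_id = pid, sequence = sample_aa(lens[i]),
        family = NA_character_)
      truth[[length(truth) + 1]] <- tibble(
        species = sp, protein_id = pid, family = "background",
        orthogroup = NA_character_, localization = NA_character_,
        catalytic = NA_character_, tep_class = NA_character_,
        tlr_class = NA_character_, rhim = NA_character_,
        relish_truncated = NA_character_)
    }
  }

  proteins <- bind_rows(proteins)
  truth <- bind_rows(truth)
  features <- bind_rows(feats_out) %>%
    select("species", "protein_id", "feature", "start", "end") %>%
    arrange(.data$species, .data$protein_id, .data$start)
  genealogy <- bind_rows(genealogy)

  # anchor references (annotated, unablated, no signal so reference
  # numbering is domain offset + 30)
  pgrp_ref <- paste0(sample_aa(30, AA_HYDROPHILIC), doms$PGRP)
  gh16_ref <- paste0(sample_aa(30, AA_HYDROPHILIC), doms$GH16)
  anchor_refs <- tibble(
    protein_id = c("PGRP_REF", "GH16_REF"),
    sequence = c(pgrp_ref, gh16_ref))

  # PSSM training alignments: 10 rows at 2% divergence from consensus
  train_paths <- list()
  for (dn in names(doms)) {
    prot_pos <- switch(dn, PGRP = PGRP_TRIAD_DOMAIN_POS,
                       GH16 = GH16_GLU_DOMAIN_POS, integer(0))
    rows <- vapply(1:10, function(i) {
      mutate_sequence(doms[[dn]], 0.02, protected = prot_pos)
    }, character(1))
    p <- file.path(dir, "domains", paste0(dn, "_train.fasta"))
    write_fasta(tibble(protein_id = paste0(dn, "_t", 1:10),
                       sequence = rows), p)
    train_paths[[dn]] <- p
  }

  rules <- default_family_rules()
  rules_path <- file.path(dir, "rules.yaml")
  write_family_rules(rules, rules_path)

  paths <- list()
  for (sp in species) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    df <- proteins[proteins$species == sp, ]
    df$family <- NA_character_  # plain proteome: no labels leak
    write_fasta(df, p)
    paths[[sp]] <- p
  }
  qpath <- file.path(dir, "query_set.fasta")
  write_fasta(proteins[proteins$species == refsp &
                         !is.na(proteins$family), ], qpath)
  write_fasta(anchor_refs, file.path(dir, "anchor_refs.fasta"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(features, file.path(dir, "truth_features.tsv"),
                   progress = FALSE)
  readr::write_tsv(genealogy, file.path(dir, "genealogy.tsv"),
                   progress = FALSE)
  writeLines(config$species_tree, file.path(dir, "species_tree.nwk"))

  invisible(list(proteins = proteins, truth = truth, features = features,
                 genealogy = genealogy, dir = dir,
                 proteome_paths = paths, query_path = qpath,
                 rules_path = rules_path,
                 anchor_refs_path = file.path(dir, "anchor_refs.fasta"),
                 train_paths = train_paths))
}

# evolve one template along the tree: birth-death copies + substitution at
# probability = branch length on unprotected positions
evolve_copies_along_tree <- function(tree, sequence, protected, birth,
                                     death) {
  ntip <- length(tree$tip.label)
  out <- list()
  descend <- function(node, lineages) {
    if (node <= ntip) {
      for (l in lineages) {
        out[[length(out) + 1]] <<- tibble(
          species = tree$tip.label[node], lineage = l$label,
          sequence = l$seq)
      }
      return(invisible())
    }
    for (e in which(tree$edge[, 1] == node)) {
      child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      nxt <- list()
      for (l in lineages) {
        k <- simulate_bd_lineage(len, birth, death)
        if (k >= 1) {
          for (d in seq_len(k)) {
            s <- mutate_sequence(l$seq, min(len, 0.95),
                                 protected = protected)
            lab <- if (k == 1) l$label else paste0(l$label, ".", d)
            nxt[[length(nxt) + 1]] <- list(label = lab, seq = s)
          }
        }
      }
      descend(child, nxt)
    }
  }
  descend(ntip + 1L, list(list(label = "a", seq = sequence)))
  if (length(out) == 0) {
    return(tibble(species = character(0), lineage = character(0),
                  sequence = character(0)))
  }
  bind_rows(out)
}

#' Default family-rule configuration
#'
#' The bundled ruleset for the six synthetic families, including the
#' degenerate motifs (GCGEQ, the 26-residue NIM pattern, the bundled RHIM
#' consensus) and the residue anchors on the annotated references
#' (`PGRP_REF` zinc-binding triad; `GH16_REF` active-site glutamates at
#' reference positions 188 and 193).
#'
#' @return A `family_rules` object.
#' @export
default_family_rules <- function() {
  rules <- tibble(
    family = c("PGRP", "GH16", "TEP", "TLR", "Relish", "Nimrod"),
    required_domains = list(
      tibble(domain = "PGRP", min_count = 1L),
      tibble(domain = "GH16", min_count = 1L),
      tibble(domain = "TEP", min_count = 1L),
      tibble(domain = c("TIR", "TM", "LRR"), min_count = c(1L, 1L, 1L)),
      tibble(domain = "RHD", min_count = 1L),
      tibble(domain = character(0), min_count = integer(0))),
    forbidden_domains = list(character(0), character(0), character(0),
                             character(0), character(0), character(0)),
    required_motifs = list(character(0), character(0), character(0),
                           character(0), character(0), "NIM"),
    residue_anchors = list("pgrp_triad", "gh16_glu_pair", character(0),
                           character(0), character(0), character(0)),
    localization = c("any", "secreted", "secreted", "transmembrane",
                     "intracellular", "any"),
    classifier = c("anchored", "anchored", "tep", "tlr", "relish", "none"),
    report_motifs = list("RHIM", character(0), character(0), character(0),
                         character(0), character(0)))
  anchors <- bind_rows(
    residue_anchor("pgrp_triad", "PGRP_REF",
                   30L + PGRP_TRIAD_DOMAIN_POS, c("C", "H", "H")),
    residue_anchor("gh16_glu_pair", "GH16_REF",
                   30L + GH16_GLU_DOMAIN_POS, c("E", "E")))
  motifs <- c(GCGEQ = "GCGEQ", NIM = NIM_PATTERN, RHIM = rhim_consensus())
  structure(list(rules = rules, anchors = anchors, motifs = motifs),
            class = "family_rules")
}
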