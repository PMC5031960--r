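# End-to-end orchestration: simulate -> build -> reconcile for gene
# families, and the rearrangement track, from one flat config.

#' Default pipeline configuration
#'
#' A single flat list of all pipeline parameters with the package
#' defaults: support thresholds 20-90, 100 bootstraps, 35%/50% homolog
#' screen, SH alpha 0.05. Any entry can be overridden via `...`.
#'
#' @param ... named overrides.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    species_tree = NULL,        # NULL = shipped default
    n_families = 5L,
    birth_rate = 0.3,
    death_rate = 0,
    root_copies = 1L,
    seq_length = 300L,
    subs_model = "LG",
    gamma_alpha = 1,
    gamma_categories = 4L,
    min_identity = 35,
    min_coverage = 0.5,
    thresholds = seq(20, 90, by = 10),
    bootstrap_reps = 100L,
    alpha = 0.05,
    n_rell = 1000L,
    max_solutions = 8L,
    candidate_cap = 200L,
    seed = 1L,
    out_dir = NULL,
    # rearrangement track
    n_genes = 30L,
    n_chromosomes = 2L,
    ops_per_branch = 2L,
    median_taxa = c("rha", "cof", "tom"),
    median_mode = "heuristic"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop_input("unknown config entries: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

resolve_species_tree <- function(cfg) {
  st <- cfg$species_tree
  if (is.null(st)) return(species_tree_default())
  if (inherits(st, "gtree")) return(st)
  if (is.character(st)) {
    if (!file.exists(st)) stop_input("species tree file not found: ", st)
    return(species_tree_default(st))
  }
  stop_input("species_tree must be NULL, a gtree, or a file path")
}

family_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 1009 + i * 97 + salt) %% 2147483647)
}

#' Run the gene-family pipeline
#'
#' Simulates `n_families` gene families with known ground truth, evolves
#' their protein sequences, builds bootstrap-annotated neighbor-joining
#' trees, generates reconciliation candidates over all support
#' thresholds and rootings, selects the best trees by SH test and
#' reconciliation cost, and reports the final event-annotated trees with
#' node supports. Rerunning with the same config is bit-identical.
#'
#' @param config a list from [pipeline_config()].
#' @return A list with `summary` (one tibble row per family: size, true
#'   and inferred event counts, candidate counts), `report` (the
#'   [family_report()] table), `families` (per-family detail: final
#'   tree, reconciliation, candidates) and `manifest`.
#' @export
run_family_pipeline <- function(config = pipeline_config()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  sp <- resolve_species_tree(cfg)
  results <- list()
  recs <- list()
  rows <- list()
  for (i in seq_len(cfg$n_families)) {
    fam_name <- sprintf("fam%02d", i)
    fam <- simulate_gene_family(sp, cfg$birth_rate, cfg$death_rate,
                                cfg$root_copies, seed = family_seed(cfg$seed, i))
    if (fam$empty) {
      rows[[i]] <- tibble::tibble(
        family = fam_name, n_genes = 0L, empty = TRUE,
        true_dup = fam$true_dup_count, true_loss = fam$true_loss_count,
        inferred_dup = NA_integer_, inferred_loss = NA_integer_,
        n_candidates = 0L, n_best = 0L
      )
      next
    }
    aln <- evolve_sequences(fam$gene_tree_true, cfg$seq_length,
                            subs_model = cfg$subs_model,
                            seed = family_seed(cfg$seed, i, 1L))
    fam$sequences <- aln
    if (length(aln) < 3) {
      # too small to build a tree: reconcile the true topology directly
      rec <- lca_reconcile(fam$gene_tree_true, sp)
      results[[fam_name]] <- list(family = fam, final = rec$gene_tree,
                                  reconciliation = rec, candidates = NULL)
      recs[[fam_name]] <- rec
      rows[[i]] <- tibble::tibble(
        family = fam_name, n_genes = length(aln), empty = FALSE,
        true_dup = fam$true_dup_count, true_loss = fam$true_loss_count,
        inferred_dup = rec$dup_count, inferred_loss = rec$loss_count,
        n_candidates = 1L, n_best = 1L
      )
      next
    }
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(paste0("stage '", name, "' failed for family ", fam_name, ": ",
                     conditionMessage(e)), parent = e)
      })
    }
    bt <- stage("treebuild", bootstrap_supports(
      aln, n_reps = cfg$bootstrap_reps, seed = family_seed(cfg$seed, i, 2L)
    ))
    cands <- stage("candidates", generate_candidates(
      bt, sp, aln, thresholds = cfg$thresholds,
      max_solutions = cfg$max_solutions, cap = cfg$candidate_cap,
      subs_model = cfg$subs_model, gamma_categories = cfg$gamma_categories,
      gamma_alpha = cfg$gamma_alpha
    ))
    best <- stage("selection", select_best(
      cands, alpha = cfg$alpha, n_rell = cfg$n_rell,
      seed = family_seed(cfg$seed, i, 3L)
    ))
    fin <- stage("final_tree", final_tree_and_support(
      best, cands, alignment = aln, n_boot = cfg$bootstrap_reps,
      seed = family_seed(cfg$seed, i, 4L)
    ))
    rec <- stage("reconcile", lca_reconcile(fin$tree, sp))
    rec$gene_tree$event_support <- fin$tree$event_support
    results[[fam_name]] <- list(family = fam, final = rec$gene_tree,
                                reconciliation = rec, candidates = cands,
                                best = best, consensus = fin$consensus,
                                node_support = fin$node_support)
    recs[[fam_name]] <- rec
    rows[[i]] <- tibble::tibble(
      family = fam_name, n_genes = length(aln), empty = FALSE,
      true_dup = fam$true_dup_count, true_loss = fam$true_loss_count,
      inferred_dup = rec$dup_count, inferred_loss = rec$loss_count,
      n_candidates = nrow(cands), n_best = nrow(best)
    )
  }
  summary <- dplyr::bind_rows(rows)
  report <- family_report(recs, species = sort(sp$label[gtree_leaves(sp)]))
  manifest <- list(
    pipeline = "family",
    package_version = as.character(utils::packageVersion("genetrace")),
    config = cfg[c("n_families", "birth_rate", "death_rate", "root_copies",
                   "seq_length", "subs_model", "gamma_alpha", "thresholds",
                   "bootstrap_reps", "alpha", "n_rell", "max_solutions",
                   "seed")],
    species_tree = gtree_newick(sp),
    n_families_run = if (nrow(summary)) sum(!summary$empty) else 0L,
    n_empty = if (nrow(summary)) sum(summary$empty) else 0L
  )
  out <- list(summary = summary, report = report, families = results,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_family_bundle(out, cfg$out_dir)
  out
}

write_family_bundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out$families)) {
    x <- out$families[[nm]]
    grafted <- graft_losses(x$reconciliation$gene_tree, x$reconciliation)
    writeLines(gtree_newick(grafted, nhx = TRUE),
               file.path(dir, paste0(nm, ".nhx")))
  }
  utils::write.table(out$report, file.path(dir, "family_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$summary, file.path(dir, "family_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run the genome-rearrangement pipeline
#'
#' Simulates genome divergence from a random ancestor by known numbers
#' of DCJ operations along the species tree (or consumes genomes
#' supplied in the config), computes all pairwise DCJ distances, and
#' infers the ancestor of three chosen taxa by the DCJ median with
#' per-branch rearrangement counts.
#'
#' @param config a list from [pipeline_config()]; `genomes` may be set
#'   to a named list of `genome` objects to skip simulation.
#' @return A list with `distances` (long tibble), `ancestor`,
#'   `branch_counts`, `simulated` (the `simulated_genomes` object or
#'   NULL) and `manifest`.
#' @export
run_rearrange_pipeline <- function(config = pipeline_config()) {
  extra <- config[setdiff(names(config), names(pipeline_config()))]
  cfg <- utils::modifyList(pipeline_config(), config[intersect(names(config), names(pipeline_config()))])
  sp <- resolve_species_tree(cfg)
  sim <- NULL
  if (!is.null(extra$genomes)) {
    genomes <- extra$genomes
  } else {
    anc <- random_genome(cfg$n_genes, cfg$n_chromosomes,
                         seed = family_seed(cfg$seed, 0L), name = "ancestor")
    sim <- simulate_genome_evolution(anc, sp, cfg$ops_per_branch,
                                     seed = family_seed(cfg$seed, 1L))
    genomes <- sim$leaves
  }
  if (length(genomes) < 2) stop_input("need at least 2 genomes")
  nms <- names(genomes)
  pairs <- utils::combn(nms, 2)
  distances <- tibble::tibble(
    genome_a = pairs[1, ], genome_b = pairs[2, ],
    dcj = apply(pairs, 2, function(p) dcj_distance(genomes[[p[1]]], genomes[[p[2]]]))
  )
  ancestor <- NULL; branch_counts <- NULL
  med_taxa <- intersect(cfg$median_taxa, nms)
  if (length(med_taxa) == 3) {
    inf <- infer_ancestor(genomes[med_taxa], mode = cfg$median_mode)
    ancestor <- inf$ancestor
    branch_counts <- inf$branch_counts
  }
  manifest <- list(
    pipeline = "rearrange",
    package_version = as.character(utils::packageVersion("genetrace")),
    config = cfg[c("n_genes", "n_chromosomes", "ops_per_branch",
                   "median_taxa", "median_mode", "seed")],
    simulated = !is.null(sim)
  )
  out <- list(distances = distances, ancestor = ancestor,
              branch_counts = branch_counts, simulated = sim,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(distances, file.path(cfg$out_dir, "dcj_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(branch_counts)) {
      utils::write.table(branch_counts,
                         file.path(cfg$out_dir, "branch_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_grimm(ancestor, file.path(cfg$out_dir, "ancestor.grimm"))
    }
    write_grimm(genomes, file.path(cfg$out_dir, "genomes.grimm"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
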