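# End-to-end orchestration: simulate (or ingest) -> filter -> groups ->
# reconcile -> ancestral states -> conservation -> contacts -> report.
# Every stage reads and writes plain-text files under the output
# directory, so any stage can be re-run independently; the whole run is a
# deterministic function of (config, seed).

#' Build a pipeline configuration
#'
#' @param out_dir output directory (created if needed)
#' @param seed master seed; every stage derives its own stream from it
#' @param sim a [simulation_config()] describing the synthetic study
#' @param stages character vector of stages to run, in dependency order
#' @param support_threshold reconciliation rearrangement threshold
#' @param min_taxa,probe_diameter interface consensus parameters
#' @param background conservation background distribution
#' @param max_gap interacting-group clustering gap
#' @return list of class "septin_pipeline_config"
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            sim = simulation_config(seed = seed),
                            stages = c("simulate", "filter", "groups",
                                       "reconcile", "asr", "conserve",
                                       "contacts", "report"),
                            support_threshold = 0.90,
                            min_taxa = 10L, probe_diameter = 0.5,
                            background = "blosum62", max_gap = 3L) {
  known <- c("simulate", "filter", "groups", "reconcile", "asr",
             "conserve", "contacts", "report")
  if (!all(stages %in% known)) {
    abort(sprintf("unknown stages: %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, support_threshold = support_threshold,
                 min_taxa = as.integer(min_taxa),
                 probe_diameter = probe_diameter,
                 background = background, max_gap = as.integer(max_gap)),
            class = "septin_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [pipeline_config()] and
#' [simulation_config()] (the latter nested under `sim:`). Unknown keys
#' are rejected.
#'
#' @param path YAML file
#' @return a "septin_pipeline_config"
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  top <- setdiff(names(y), c(names(formals(pipeline_config)), "sim"))
  if (length(top) > 0) {
    abort(sprintf("unknown config keys: %s", paste(top, collapse = ", ")))
  }
  sim_args <- y$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad) > 0) {
    abort(sprintf("unknown sim config keys: %s",
                  paste(bad, collapse = ", ")))
  }
  y$sim <- do.call(simulation_config,
                   c(sim_args, list(seed = y$seed %||% 1L)))
  do.call(pipeline_config, y)
}

pfile <- function(config, ...) file.path(config$out_dir, ...)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order. The `simulate`
#' stage writes a complete synthetic dataset (species tree, per-Group
#' gene families, proteome, structure panel, truth). Analysis stages
#' consume only files, so they can equally run on user-supplied inputs
#' placed at the same paths. A second run with the same config and seed
#' reproduces every output byte-identically (wall-clock timings go to a
#' separate log file, not into the report).
#'
#' @param config a [pipeline_config()]
#' @return the run report (named list), invisibly also written as
#'   `report.json` and `report.txt` under the output directory
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "septin_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    seed = config$seed, n_taxa = config$sim$n_taxa,
    n_groups = config$sim$n_groups,
    support_threshold = config$support_threshold,
    min_taxa = config$min_taxa,
    probe_diameter = config$probe_diameter))
  timings <- c()
  for (stage in config$stages) {
    t0 <- Sys.time()
    report <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, report),
             filter = stage_filter(config, report),
             groups = stage_groups(config, report),
             reconcile = stage_reconcile(config, report),
             asr = stage_asr(config, report),
             conserve = stage_conserve(config, report),
             contacts = stage_contacts(config, report),
             report = report),
      error = function(e) {
        writeLines(sprintf("FAILED at stage '%s': %s", stage,
                           conditionMessage(e)),
                   pfile(config, "FAILED"))
        stop(errorCondition(
          sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = c("septinevo_stage_failure", "septinevo_error")))
      })
    timings[stage] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  jsonlite::write_json(report, pfile(config, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), pfile(config, "report.txt"))
  writeLines(sprintf("%s\t%.3f", names(timings), timings),
             pfile(config, "timings.log"))
  invisible(report)
}

format_report <- function(report) {
  c("septinevo pipeline report",
    "=========================",
    vapply(names(report$counts %||% list()), function(k) {
      sprintf("%-28s %s", k, report$counts[[k]])
    }, character(1)))
}

stage_simulate <- function(config, report) {
  sim <- config$sim
  sp <- simulate_species_tree(sim$n_taxa, sim$birth_rate,
                              seed = derive_seed(config$seed, 1L),
                              root_age = sim$root_age)
  ape::write.tree(sp, pfile(config, "species_tree.nwk"))
  # one gene family per septin Group; resample seeds on total extinction
  fams <- list()
  for (g in seq_len(sim$n_groups)) {
    fam <- NULL
    for (try in 0:49) {
      fam <- tryCatch(
        simulate_gene_family(sp, sim$dup_rate, sim$loss_rate,
                             seed = derive_seed(config$seed,
                                                100L + 50L * g + try)),
        septinevo_empty_family = function(e) NULL)
      if (!is.null(fam)) break
    }
    if (is.null(fam)) abort("gene family extinct in every resample")
    fams[[g]] <- fam
    ape::write.tree(fam$tree,
                    pfile(config, sprintf("gene_tree_grp%d.nwk", g)))
    write_tsv(fam$truth$events,
              pfile(config, sprintf("gene_events_grp%d.tsv", g)))
  }
  prot <- simulate_septin_proteome(sim, seed = derive_seed(config$seed, 2L))
  write_proteome(prot$records, pfile(config, "proteome.fasta"),
                 pfile(config, "proteome_domains.tsv"))
  write_tsv(prot$truth, pfile(config, "proteome_truth.tsv"))
  st <- simulate_dimer_structures(sim, seed = derive_seed(config$seed, 3L))
  dir.create(pfile(config, "structures"), showWarnings = FALSE)
  manifest <- data.frame(file = character(0), taxon = character(0),
                         template = character(0))
  for (s in st$structures) {
    fn <- sprintf("structures/%s.pdb", gsub("[:]", "_", s$id))
    write_structure_pdb(s, pfile(config, fn))
    manifest <- rbind(manifest, data.frame(file = fn, taxon = s$taxon,
                                           template = s$template))
  }
  write_tsv(manifest, pfile(config, "structure_manifest.tsv"))
  write_alignment(st$alignment, pfile(config, "structure_alignment.fasta"))
  jsonlite::write_json(
    list(planted = st$truth$planted,
         taxa = st$truth$taxa),
    pfile(config, "structure_truth.json"), auto_unbox = TRUE, digits = NA)
  # presence/absence characters: taxon has the Group iff a gene survived
  taxa <- sp$tip.label
  chars <- vapply(fams, function(fam) {
    as.integer(taxa %in% leaf_taxon(fam$tree$tip.label))
  }, integer(length(taxa)))
  rownames(chars) <- taxa
  colnames(chars) <- sprintf("grp%d", seq_len(sim$n_groups))
  write_character_matrix(chars, pfile(config, "group_presence.tsv"))
  report$counts <- c(report$counts,
                     list(simulated_gene_families = length(fams),
                          simulated_proteins = nrow(prot$records),
                          simulated_structures = length(st$structures)))
  report
}

stage_filter <- function(config, report) {
  records <- read_proteome(pfile(config, "proteome.fasta"),
                           pfile(config, "proteome_domains.tsv"))
  res <- filter_proteome(records)
  write_tsv(res$decisions, pfile(config, "filter_decisions.tsv"))
  write_proteome(res$retained, pfile(config, "retained.fasta"),
                 pfile(config, "retained_domains.tsv"))
  report$counts <- c(report$counts,
                     list(proteins_in = nrow(records),
                          proteins_retained = nrow(res$retained)))
  report
}

stage_groups <- function(config, report) {
  n_groups <- config$sim$n_groups
  trees <- lapply(seq_len(n_groups), function(g) {
    ape::read.tree(pfile(config, sprintf("gene_tree_grp%d.nwk", g)))
  })
  # combined tree: per-family subtrees joined on a backbone, leaves
  # prefixed by family; anchors = first leaf of each family
  sub_nwk <- vapply(seq_len(n_groups), function(g) {
    tr <- trees[[g]]
    tr$tip.label <- sprintf("grp%d.%s", g, tr$tip.label)
    tr$node.label <- NULL
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  combined <- sub_nwk[1]
  for (g in seq_len(n_groups)[-1]) {
    combined <- sprintf("(%s,%s):1", combined, sub_nwk[g])
  }
  ctree <- ape::read.tree(text = paste0(combined, ";"))
  anchors <- setNames(sprintf("grp%d", seq_len(n_groups)),
                      vapply(seq_len(n_groups), function(g) {
                        sprintf("grp%d.%s", g, trees[[g]]$tip.label[1])
                      }, character(1)))
  assignment <- assign_groups(ctree, anchors)
  write_tsv(data.frame(leaf = names(assignment), group = assignment),
            pfile(config, "group_assignment.tsv"))
  report$counts <- c(report$counts, list(
    leaves_classified = sum(assignment != "UNCLASSIFIED"),
    leaves_unclassified = sum(assignment == "UNCLASSIFIED")))
  report
}

stage_reconcile <- function(config, report) {
  sp <- ape::read.tree(pfile(config, "species_tree.nwk"))
  n_groups <- config$sim$n_groups
  all_events <- list()
  profiles <- list()
  tot_dup <- 0; tot_loss <- 0
  for (g in seq_len(n_groups)) {
    gt <- ape::read.tree(pfile(config, sprintf("gene_tree_grp%d.nwk", g)))
    res <- reconcile(gt, sp,
                     support_threshold = config$support_threshold)
    prof <- copy_number_profile(res)
    profiles[[g]] <- prof
    tot_dup <- tot_dup + mean(vapply(res, `[[`, numeric(1),
                                     "n_duplications"))
    tot_loss <- tot_loss + mean(vapply(res, `[[`, numeric(1), "n_losses"))
    ev <- res[[1]]$event_map
    ev$group <- sprintf("grp%d", g)
    all_events[[g]] <- ev
    write_tsv(data.frame(branch = names(prof), mean_copies = prof),
              pfile(config, sprintf("copy_number_grp%d.tsv", g)))
  }
  write_tsv(do.call(rbind, all_events), pfile(config, "events.tsv"))
  total <- Reduce(`+`, profiles)
  write_tsv(data.frame(branch = names(total), mean_copies = total),
            pfile(config, "copy_number_total.tsv"))
  report$counts <- c(report$counts,
                     list(duplications = tot_dup, losses = tot_loss))
  report
}

stage_asr <- function(config, report) {
  sp <- ape::read.tree(pfile(config, "species_tree.nwk"))
  chars <- read_character_matrix(pfile(config, "group_presence.tsv"))
  fits <- list()
  recon <- list()
  for (g in colnames(chars)) {
    x <- setNames(chars[, g], rownames(chars))
    f1 <- fit_mk(sp, x, "MK1")
    f2 <- fit_mk(sp, x, "MK2")
    w <- wilks_test(f1$logLik, f2$logLik)
    fits[[g]] <- data.frame(group = g, model = c("MK1", "MK2"),
                            q01 = c(f1$model$q01, f2$model$q01),
                            q10 = c(f1$model$q10, f2$model$q10),
                            lnL = c(f1$logLik, f2$logLik),
                            LRT = w$statistic, p = w$p_value)
    mr <- marginal_reconstruction(sp, x, f1$model)
    mr$group <- g
    recon[[g]] <- mr
  }
  write_tsv(do.call(rbind, fits), pfile(config, "mk_fits.tsv"))
  rec <- do.call(rbind, recon)
  write_tsv(rec, pfile(config, "ancestral_states.tsv"))
  report$counts <- c(report$counts, list(
    characters = ncol(chars),
    resolved_nodes = sum(rec$resolved),
    mk1_rejected = sum(vapply(fits, function(f) f$p[1] < 0.05,
                              logical(1)))))
  report
}

stage_conserve <- function(config, report) {
  aln <- read_alignment(pfile(config, "structure_alignment.fasta"))
  prof <- conservation_profile(aln, background = config$background)
  refmap <- map_to_reference(aln, "REF")
  cols <- seq_along(prof)
  ref_pos <- rep(NA_integer_, length(cols))
  ref_pos[as.integer(names(refmap$col_to_res))] <- refmap$col_to_res
  write_tsv(data.frame(column = cols, ref_position = ref_pos,
                       score = as.numeric(prof)),
            pfile(config, "conservation.tsv"))
  report$counts <- c(report$counts, list(
    alignment_columns = length(cols),
    columns_above_0.5 = sum(prof > 0.5)))
  report
}

stage_contacts <- function(config, report) {
  manifest <- read.delim(pfile(config, "structure_manifest.tsv"),
                         stringsAsFactors = FALSE)
  aln <- read_alignment(pfile(config, "structure_alignment.fasta"))
  structures <- lapply(seq_len(nrow(manifest)), function(i) {
    read_structure_pdb(pfile(config, manifest$file[i]),
                       taxon = manifest$taxon[i],
                       template = manifest$template[i])
  })
  tab <- structure_residue_table(structures,
                                 probe_diameter = config$probe_diameter)
  cons <- aggregate_interfaces(tab, aln, "REF",
                               n_taxa = length(unique(manifest$taxon)),
                               min_taxa = config$min_taxa)
  write_tsv(cons, pfile(config, "interface_consensus.tsv"))
  hitsG <- cons$position[cons$consensus & cons$interface == "G"]
  hitsNC <- cons$position[cons$consensus & cons$interface == "NC"]
  clusters <- rbind(
    cbind(interface = "G", interface_cluster(hitsG, config$max_gap)),
    cbind(interface = "NC", interface_cluster(hitsNC, config$max_gap)))
  write_tsv(clusters, pfile(config, "interface_clusters.tsv"))
  # logo matrices over the full panel at consensus positions
  groups <- setNames(rep("all", sum(names(aln) != "REF")),
                     setdiff(names(aln), "REF"))
  for (iface in c("G", "NC")) {
    pos <- if (iface == "G") hitsG else hitsNC
    if (length(pos) == 0) next
    prof <- group_frequency_profiles(aln, groups, pos, "REF")
    freq <- prof$all$freq
    write_tsv(data.frame(residue = rownames(freq), freq,
                         check.names = FALSE),
              pfile(config, sprintf("logo_%s.tsv", iface)))
  }
  report$counts <- c(report$counts, list(
    consensus_G = length(hitsG), consensus_NC = length(hitsNC),
    interacting_groups = nrow(clusters)))
  report
}
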