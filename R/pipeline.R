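# Stage orchestration: simulate -> dca -> filter -> dock -> evaluate, with
# explicit on-disk artifacts, a frozen config snapshot, and line logging.

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, sprintf(...)))
}

#' Pipeline configuration
#'
#' Collects every tunable of the five stages with its default. For synthetic
#' runs the `paths` entries stay `NULL` and the `simulate` stage writes the
#' inputs; for runs on real data set `paths$msa`, `paths$pdb_a` /
#' `paths$chain_a`, `paths$pdb_b` / `paths$chain_b`, optional homodimer
#' assemblies, and the ligand-site residue lists, then skip `simulate`.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param ... named overrides for nested entries, e.g.
#'   `dock = list(n_replicas = 5)`.
#' @return A `coevodock_config` list.
#' @export
coevodock_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    paths = list(msa = NULL, pdb_a = NULL, chain_a = NULL, pdb_b = NULL,
                 chain_b = NULL, homodimer_a = NULL, homodimer_b = NULL,
                 ligand_sites_a = NULL, ligand_sites_b = NULL),
    simulate = list(n = 30L, n_contacts = 8L, design_distance = 12,
                    M = 1130L, q = 8L, strength = 1.0),
    dca = list(x = 0.8, lambda = NULL, max_gap_fraction = 0.5,
               min_separation = 5L),
    filter = list(K = NULL, exposure_threshold = 0.05,
                  monomer_cutoff = 5, homodimer_cutoff = 5,
                  use_exclusions = FALSE, identity_floor = 0.9),
    dock = list(r_couple = 10, r_cluster = 12, k = 1, k_c = 1,
                gauss_depth = 1, gauss_r0 = 8, gauss_width = 2,
                n_replicas = 10L, separation = 75, contact_cutoff = NULL,
                t_init = 1.2, t_final = 0.2, nsteps = 2e5, dt = 5e-4,
                friction = 1.0, clash_threshold = 3.8),
    evaluate = list(within = 10, connect_radius = 15))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  if (is.null(cfg$filter$K))
    cfg$filter$K <- if (is.null(cfg$paths$msa))
      cfg$simulate$n_contacts %/% 2L else 20L
  class(cfg) <- "coevodock_config"
  cfg
}

write_config_snapshot <- function(config, out_dir) {
  snap <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(snap, file.path(out_dir, "config_snapshot.yaml"))
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing input artifact '", basename(path),
         "': run stage '", produced_by, "' first")
  path
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Write one chain as a C-alpha PDB file
#'
#' @param chain a `chain`.
#' @param path output path.
#' @param chain_id chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, chain_id = "A") {
  con <- file(path, "w")
  on.exit(close(con))
  resn <- bio3d::aa123(chain$seq1)
  resn[is.na(resn)] <- "UNK"
  for (k in seq_len(chain$n)) {
    resno <- suppressWarnings(as.integer(gsub("[^0-9-]", "",
                                              chain$res_id[k])))
    if (is.na(resno)) resno <- k
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      k, "CA", resn[k], chain_id, resno,
      chain$ca[k, 1], chain$ca[k, 2], chain$ca[k, 3], 1, 0), con)
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

load_input_chains <- function(config, out_dir) {
  p <- config$paths
  if (!is.null(p$pdb_a)) {
    a <- read_structure(p$pdb_a, p$chain_a)
    b <- read_structure(p$pdb_b, p$chain_b)
    sa <- as.character(p$ligand_sites_a)
    sb <- as.character(p$ligand_sites_b)
  } else {
    truth <- jsonlite::read_json(
      need_artifact(file.path(out_dir, "truth.json"), "simulate"),
      simplifyVector = TRUE)
    a <- read_structure(file.path(out_dir, "chain_a.pdb"), "A")
    b <- read_structure(file.path(out_dir, "chain_b.pdb"), "B")
    sa <- as.character(truth$ligand_sites)
    sb <- as.character(truth$ligand_sites)
  }
  list(chain_a = set_ligand_sites(a, sa), chain_b = set_ligand_sites(b, sb))
}

load_msa_input <- function(config, out_dir) {
  if (!is.null(config$paths$msa)) read_msa(config$paths$msa)
  else read_msa(need_artifact(file.path(out_dir, "msa.fasta"), "simulate"))
}

stage_simulate <- function(config, out_dir) {
  sim <- config$simulate
  toy <- make_toy_complex(toy_complex_spec(
    n = sim$n, n_contacts = sim$n_contacts,
    design_distance = sim$design_distance, seed = config$seed))
  pairs <- unique(data.frame(i = pmin(toy$contacts$i, toy$contacts$j),
                             j = pmax(toy$contacts$i, toy$contacts$j)))
  couplings <- data.frame(i = pairs$i, j = pairs$j, strength = sim$strength)
  al <- sample_potts_msa(potts_spec(L = sim$n, q = sim$q, M = sim$M,
                                    couplings = couplings,
                                    seed = config$seed))
  # tie the toy chains to the family: chain sequence = alignment consensus
  cons <- msa_consensus(al)
  chain_a <- new_chain(toy$chain_a$ca, cons,
                       ligand_site_residues = toy$chain_a$ligand_site_residues)
  chain_b <- new_chain(toy$chain_b$ca, cons,
                       ligand_site_residues = toy$chain_b$ligand_site_residues)
  write_msa(al, file.path(out_dir, "msa.fasta"))
  write_chain_pdb(chain_a, file.path(out_dir, "chain_a.pdb"), "A")
  write_chain_pdb(chain_b, file.path(out_dir, "chain_b.pdb"), "B")
  write_json_report(
    list(contacts = toy$contacts, planted = couplings,
         ligand_sites = toy$spec$ligand_sites,
         design_distance = toy$spec$design_distance,
         ligand_distance = toy$ligand_distance, seed = config$seed),
    file.path(out_dir, "truth.json"))
  log_msg("INFO", "simulate: %d-residue toy complex, %d contacts, M=%d MSA",
          sim$n, nrow(toy$contacts), al$M)
  invisible(out_dir)
}

stage_dca <- function(config, out_dir) {
  al <- load_msa_input(config, out_dir)
  al <- filter_sequences(al, config$dca$max_gap_fraction)
  w <- compute_weights(al, x = config$dca$x)
  fr <- compute_frequencies(al, w, lambda = config$dca$lambda)
  cp <- infer_couplings(fr)
  di <- di_matrix(cp, fr)
  ranked <- rank_pairs(di, min_separation = config$dca$min_separation)
  utils::write.table(di, file.path(out_dir, "di_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_pairs_tsv(ranked, file.path(out_dir, "ranked_pairs.tsv"))
  log_msg("INFO", "dca: M=%d Meff=%.1f lambda=%.1f, %d ranked pairs",
          al$M, w$Meff, fr$lambda, nrow(ranked))
  invisible(out_dir)
}

stage_filter <- function(config, out_dir) {
  ranked <- utils::read.table(
    need_artifact(file.path(out_dir, "ranked_pairs.tsv"), "dca"),
    header = TRUE, sep = "\t")
  al <- load_msa_input(config, out_dir)
  chains <- load_input_chains(config, out_dir)
  map1 <- map_columns_to_chain(al, chains$chain_a,
                               identity_floor = config$filter$identity_floor)
  map2 <- map_columns_to_chain(al, chains$chain_b,
                               identity_floor = config$filter$identity_floor)
  monomer <- list(NULL, NULL); sasa <- list(NULL, NULL)
  homod <- list(NULL, NULL)
  if (isTRUE(config$filter$use_exclusions)) {
    monomer <- list(
      compute_contact_map(chains$chain_a, config$filter$monomer_cutoff),
      compute_contact_map(chains$chain_b, config$filter$monomer_cutoff))
    if (has_heavy_atoms(chains$chain_a))
      sasa <- list(compute_sasa(chains$chain_a), compute_sasa(chains$chain_b))
    p <- config$paths
    if (!is.null(p$homodimer_a)) {
      ha <- lapply(p$homodimer_a$chains, function(cid)
        read_structure(p$homodimer_a$path, cid))
      homod[[1]] <- homodimer_contacts(ha[[1]], ha[[2]],
                                       config$filter$homodimer_cutoff)
    }
    if (!is.null(p$homodimer_b)) {
      hb <- lapply(p$homodimer_b$chains, function(cid)
        read_structure(p$homodimer_b$path, cid))
      homod[[2]] <- homodimer_contacts(hb[[1]], hb[[2]],
                                       config$filter$homodimer_cutoff)
    }
  }
  cand <- filter_couplings(ranked, map1, map2, monomer_maps = monomer,
                           sasa = sasa, homodimer_maps = homod,
                           K = config$filter$K,
                           exposure_threshold = config$filter$exposure_threshold)
  write_candidates(cand, file.path(out_dir, "candidates.tsv"),
                   file.path(out_dir, "filter_audit.tsv"))
  log_msg("INFO", "filter: %d candidate orientations from K=%d pairs",
          nrow(cand), config$filter$K)
  invisible(out_dir)
}

read_candidates_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(res_chain1 = "character",
                                         res_chain2 = "character"))
  class(df) <- c("candidate_set", "data.frame")
  df
}

stage_dock <- function(config, out_dir) {
  cand <- read_candidates_tsv(
    need_artifact(file.path(out_dir, "candidates.tsv"), "filter"))
  chains <- load_input_chains(config, out_dir)
  dk <- config$dock
  cutoff_for <- function(chain) {
    if (!is.null(dk$contact_cutoff)) dk$contact_cutoff
    else if (has_heavy_atoms(chain)) 4.5 else 8.0
  }
  top_a <- build_sbm(chains$chain_a, contact_cutoff = cutoff_for(chains$chain_a))
  top_b <- build_sbm(chains$chain_b, contact_cutoff = cutoff_for(chains$chain_b))
  restr <- build_restraints(cand, chains$chain_a, chains$chain_b,
                            r_couple = dk$r_couple, r_cluster = dk$r_cluster,
                            k = dk$k, k_c = dk$k_c,
                            gauss_depth = dk$gauss_depth,
                            gauss_r0 = dk$gauss_r0,
                            gauss_width = dk$gauss_width)
  sched <- anneal_schedule(t_init = dk$t_init, t_final = dk$t_final,
                           nsteps = dk$nsteps, dt = dk$dt,
                           friction = dk$friction)
  ens <- run_ensemble(top_a, top_b, restr, sched,
                      n_replicas = dk$n_replicas, base_seed = config$seed,
                      separation = dk$separation,
                      clash_threshold = dk$clash_threshold)
  best <- select_model(ens)
  write_docked_pdb(best, file.path(out_dir, "model.pdb"))
  summary <- lapply(ens, function(m) list(
    seed = m$seed, clash_count = m$clash$count,
    violation_energy = m$violation_energy,
    restraint_satisfaction = mean(
      m$restraint$pair_distances <= restr$pairs$r_upper + restr$tolerance),
    cluster_distance = m$restraint$cluster_distance,
    q_a = m$q_a, q_b = m$q_b, energy = m$energy))
  write_json_report(list(selected_seed = best$seed, replicas = summary,
                         failures = attr(ens, "failures")),
                    file.path(out_dir, "ensemble.json"))
  log_msg("INFO", "dock: %d replicas, selected seed %d (%d clashes)",
          length(ens), best$seed, best$clash$count)
  invisible(out_dir)
}

stage_evaluate <- function(config, out_dir) {
  cand <- read_candidates_tsv(
    need_artifact(file.path(out_dir, "candidates.tsv"), "filter"))
  chains <- load_input_chains(config, out_dir)
  model <- read_docked_pdb(
    need_artifact(file.path(out_dir, "model.pdb"), "dock"),
    sites_a = chains$chain_a$ligand_site_residues,
    sites_b = chains$chain_b$ligand_site_residues)
  model$clash <- count_clashes(model, config$dock$clash_threshold)
  restr <- build_restraints(cand, chains$chain_a, chains$chain_b,
                            r_couple = config$dock$r_couple,
                            r_cluster = config$dock$r_cluster,
                            k = config$dock$k, k_c = config$dock$k_c)
  report <- evaluate_model(model, cand, restr,
                           within = config$evaluate$within,
                           connect_radius = config$evaluate$connect_radius)
  out <- unclass(report)
  truth_path <- file.path(out_dir, "truth.json")
  if (is.null(config$paths$msa) && file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    out$interface_rmsd <- interface_rmsd(model, chains$chain_a$ca,
                                         chains$chain_b$ca,
                                         truth$contacts)
    out$design_distance <- truth$design_distance
  }
  utils::write.table(pair_distance_table(model, cand),
                     file.path(out_dir, "pair_distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json_report(out, file.path(out_dir, "report.json"))
  log_msg("INFO", "evaluate: cluster distance %.2f A, %0.2f of pairs within %g A",
          out$cluster_distance, out$fraction_within, config$evaluate$within)
  invisible(out_dir)
}

#' Run one pipeline stage
#'
#' Stages communicate through files in `out_dir` (no hidden state); a stage
#' whose upstream artifact is missing stops with a dependency error naming
#' the stage to run first. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param stage one of `"simulate"`, `"dca"`, `"filter"`, `"dock"`,
#'   `"evaluate"`.
#' @param config a [coevodock_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_stage <- function(stage, config = coevodock_config(), out_dir) {
  stage <- match.arg(stage, c("simulate", "dca", "filter", "dock", "evaluate"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config_snapshot(config, out_dir)
  switch(stage,
         simulate = stage_simulate(config, out_dir),
         dca = stage_dca(config, out_dir),
         filter = stage_filter(config, out_dir),
         dock = stage_dock(config, out_dir),
         evaluate = stage_evaluate(config, out_dir))
}

#' Run the full pipeline
#'
#' Runs `simulate` (synthetic mode only), then `dca`, `filter`, `dock`,
#' `evaluate`.
#'
#' @inheritParams run_stage
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = coevodock_config(), out_dir) {
  stages <- c(if (is.null(config$paths$msa)) "simulate",
              "dca", "filter", "dock", "evaluate")
  for (s in stages) run_stage(s, config, out_dir)
  invisible(out_dir)
}
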