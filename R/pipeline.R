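#' Default pipeline configuration
#'
#' Every stage parameter with its recorded default: the contact criterion
#' (4.5 A, persistence > 0.75), display mask 0.4, landscape temperature
#' 300 K, nonpolar constants gamma = 0.0072 kcal/(mol A^2) and b = 0, the
#' clustering cutoff, and the synthetic two-state demo generator settings.
#' `validate_config()` fills these into any partial config.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "mdensemble-report",
    stages = list(rmsd = TRUE, pca = TRUE, dccm = TRUE, network = TRUE,
                  dcna = TRUE, solvation = TRUE, cluster = TRUE,
                  gbsa = TRUE),
    synthetic = list(
      n_particles = 24L, block_size = 12L, n_frames = 400L,
      amplitude = 0.3, intra_correlation = 0.7,
      inter_correlation_bound = -0.2, inter_correlation_unbound = -0.5,
      state_shift = 6.0, mixture_weight = 0.5,
      solvation = list(shell_radius = 2.35, occupancy = 7L,
                       box = c(30, 30, 30), bulk_density = 0.008,
                       jitter = 0.05, n_frames = 60L)),
    rmsd = list(discard = 0L),
    pca = list(bins = 30L, temperature = 300, basin_depth = 1.2),
    dccm = list(mask = 0.4, anti_cutoff = -0.4),
    network = list(cutoff = 4.5, persistence = 0.75, min_community = 3L,
                   weighted_betweenness = TRUE),
    solvation = list(bin_width = 0.05, r_max = 8, coordination_cutoff = 3.0),
    cluster = list(cutoff = 2.0, stride = 1L),
    gbsa = list(solvent_dielectric = 78.5, solute_dielectric = 1,
                gamma = 0.0072, b = 0, probe = 1.4, n_points = 400L,
                offset = 0.09, scale = 0.8,
                ion_rstar = 1.79, ion_epsilon = 0.0140)
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills every missing key from
#' [default_config()], and rejects unknown keys with a nearest-match hint
#' and out-of-range parameters with an itemized error list. The resolved
#' config round-trips losslessly through YAML.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The fully resolved config (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML mapping or a named list")
  def <- default_config()
  errs <- character(0)
  check_keys <- function(x, ref, path = "") {
    unknown <- setdiff(names(x), names(ref))
    for (u in unknown) {
      d <- utils::adist(u, names(ref))
      hint <- if (min(d) <= 2)
        paste0("; did you mean '", names(ref)[which.min(d)], "'?") else ""
      errs <<- c(errs, paste0("unknown key '", path, u, "'", hint))
    }
    for (k in intersect(names(x), names(ref)))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]))
        check_keys(x[[k]], ref[[k]], paste0(path, k, "."))
  }
  check_keys(cfg, def)
  merged <- modifyList(def, cfg)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(merged$network$persistence >= 0 && merged$network$persistence < 1,
      "network.persistence must be a fraction in [0, 1)")
  chk(merged$network$cutoff > 0, "network.cutoff must be positive")
  chk(merged$dccm$mask >= 0 && merged$dccm$mask <= 1,
      "dccm.mask must be in [0, 1]")
  chk(merged$pca$temperature > 0, "pca.temperature must be positive")
  chk(merged$synthetic$mixture_weight > 0 && merged$synthetic$mixture_weight < 1,
      "synthetic.mixture_weight must be strictly between 0 and 1")
  chk(merged$cluster$cutoff > 0, "cluster.cutoff must be positive")
  chk(merged$solvation$bin_width > 0, "solvation.bin_width must be positive")
  chk(merged$gbsa$gamma >= 0, "gbsa.gamma must be non-negative")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(merged, class = c("pipeline_config", "list"))
}

#' Write a resolved configuration back to YAML
#' @param config A `pipeline_config` (or list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Block-structured target correlation for the demo states.
.demo_correlation <- function(n, block, intra, inter) {
  C <- matrix(0, n, n)
  b1 <- seq_len(block); b2 <- setdiff(seq_len(n), b1)
  C[b1, b1] <- intra; C[b2, b2] <- intra
  C[b1, b2] <- inter; C[b2, b1] <- inter
  diag(C) <- 1
  C
}

# Two compact particle blocks meeting at an interface: within a block,
# nearest grid neighbors sit at 4.2 A (inside the 4.5 A contact cutoff),
# and the blocks touch along x so inter-block contacts exist in the bound
# reference and are severed by the unbound state's interface shift.
.demo_reference <- function(n, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  half <- ceiling(n / 2)
  grid_block <- function(m, origin) {
    nx <- ceiling(m / 4)
    # y/z vary fastest so sequence-neighbor exclusion removes intra-slab
    # edges, leaving the x-direction lattice to hold each block together
    g <- expand.grid(y = 1:2, z = 1:2, x = seq_len(nx))[seq_len(m), ]
    sweep(as.matrix(g[, c("x", "y", "z")]) * 4.2, 2, origin, "+")
  }
  a <- grid_block(half, c(0, 0, 0))
  b <- grid_block(n - half, c(max(a[, 1]), 0, 0))
  rbind(a, b) + matrix(runif(3 * n, -0.15, 0.15), ncol = 3)
}

#' Run the full two-state comparison pipeline on synthetic ensembles
#'
#' Orchestrates every analysis stage on a generated two-state system
#' ("bound" vs "unbound" differ in their inter-block correlation and a
#' rigid shift of the second block): superposition/RMSD, covariance PCA
#' with a free-energy landscape and basin count, DCCM with inter-domain
#' summaries, the persistence-contact network with Girvan-Newman
#' communities, the difference contact network, an ion solvation-shell
#' analysis, GROMOS clustering with representative extraction and a
#' cross-state RMSD, and the MM-GBSA decomposition with a state
#' comparison. Stages run in dependency order; a failed stage marks its
#' dependents blocked instead of silently skipping them. With a fixed
#' config and seed the numeric payload is identical across runs.
#'
#' @param config A `pipeline_config`, a path to one, or a partial list.
#' @param output_dir Override the config's output directory; when omitted
#'   the config's `output_dir` is used, and `NULL` writes nothing to disk.
#' @return An `analysis_report`: list with `results` (one block per enabled
#'   stage), `provenance` (seed, resolved config, package version),
#'   `warnings`, `errors`.
#' @export
run_pipeline <- function(config = list(), output_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  seed <- as.integer(cfg$seed)
  syn <- cfg$synthetic
  N <- syn$n_particles; blk <- syn$block_size
  ref_bound <- .demo_reference(N, seed)
  shift <- matrix(0, N, 3)
  shift[(blk + 1):N, 1] <- syn$state_shift
  ref_unbound <- ref_bound + shift
  blockA <- seq_len(blk); blockB <- setdiff(seq_len(N), blockA)
  specs <- list(
    bound = ensemble_spec(ref_bound,
                          .demo_correlation(N, blk, syn$intra_correlation,
                                            syn$inter_correlation_bound),
                          syn$amplitude, syn$n_frames, seed),
    unbound = ensemble_spec(ref_unbound,
                            .demo_correlation(N, blk, syn$intra_correlation,
                                              syn$inter_correlation_unbound),
                            syn$amplitude, syn$n_frames, seed + 1L))
  trajs <- lapply(specs, generate_correlated_ensemble)
  reference <- frame_structure(trajs$bound, 1L)
  reference$xyz <- as.numeric(t(ref_bound))
  sel_all <- seq_len(N)
  results <- list()
  warns <- character(0)
  errors <- list()
  blocked <- character(0)
  run_stage <- function(name, deps, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    if (length(intersect(deps, c(names(errors), blocked)))) {
      blocked <<- c(blocked, name)
      results[[name]] <<- list(status = "blocked",
                               blocked_by = intersect(deps, c(names(errors), blocked)))
      return(invisible(NULL))
    }
    out <- tryCatch(withCallingHandlers(fun(), warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(out, "error")) {
      errors[[name]] <<- conditionMessage(out)
      results[[name]] <<- list(status = "error",
                               message = conditionMessage(out))
    } else {
      results[[name]] <<- c(list(status = "ok"), out)
    }
    invisible(NULL)
  }

  run_stage("rmsd", character(0), function() {
    lapply(trajs, function(tr) {
      s <- rmsd_series(tr, reference, sel_all, discard = cfg$rmsd$discard)
      list(mean = attr(s, "mean"), sd = attr(s, "sd"))
    })
  })
  run_stage("pca", character(0), function() {
    out <- lapply(names(trajs), function(st) {
      pm <- covariance_pca(trajs[[st]], sel_all, reference = NULL)
      pr <- project_frames(trajs[[st]], pm, 2)
      fg <- fel(pr, cfg$pca$temperature, cfg$pca$bins)
      bas <- basin_detect(fg, cfg$pca$basin_depth)
      list(pc12_fraction = sum(pm$fractions[1:2]),
           eigen_top = pm$values[1:4], n_basins = nrow(bas))
    })
    names(out) <- names(trajs)
    # two-state mixture for the substate landscape
    mix <- generate_two_state_ensemble(specs$bound, specs$unbound,
                                       cfg$synthetic$mixture_weight,
                                       n_frames = syn$n_frames,
                                       seed = seed + 2L)
    pm <- covariance_pca(mix, sel_all, reference = NULL)
    pr <- project_frames(mix, pm, 2)
    bas <- basin_detect(fel(pr, cfg$pca$temperature, cfg$pca$bins),
                        cfg$pca$basin_depth)
    out$two_state_mixture <- list(n_basins = nrow(bas))
    out
  })
  dccm_env <- new.env()
  run_stage("dccm", character(0), function() {
    out <- list()
    for (st in names(trajs)) {
      cm <- dccm(trajs[[st]], sel_all, reference = NULL)
      assign(st, cm, envir = dccm_env)
      s <- interdomain_summary(cm, blockA, blockB, cfg$dccm$anti_cutoff)
      out[[st]] <- list(interdomain_mean = s$mean,
                        fraction_anti = s$fraction_anti,
                        masked_surviving = sum(!is.na(mask_dccm(cm, cfg$dccm$mask))))
    }
    out
  })
  net_env <- new.env()
  run_stage("network", "dccm", function() {
    cms <- mget(names(trajs), envir = dccm_env)
    out <- list()
    for (st in names(trajs)) {
      g <- contact_persistence(trajs[[st]], cfg$network$cutoff,
                               cfg$network$persistence)
      g <- weight_edges(g, cms[[st]])
      part <- girvan_newman(g, cfg$network$min_community,
                            cfg$network$weighted_betweenness)
      assign(paste0("net_", st), list(graph = g, partition = part),
             envir = net_env)
      out[[st]] <- list(n_edges = nrow(g$edges),
                        n_communities = length(part$sizes),
                        modularity = part$modularity)
    }
    out
  })
  run_stage("dcna", "network", function() {
    a <- get("net_bound", envir = net_env)
    b <- get("net_unbound", envir = net_env)
    dn <- difference_network(a$graph, a$partition, b$graph)
    list(max_abs_change = max(abs(dn$change)),
         total_change = sum(dn$change[upper.tri(dn$change)]))
  })
  run_stage("solvation", character(0), function() {
    sv <- syn$solvation
    toy <- generate_solvation_toy(solvation_toy_spec(
      shell_radius = sv$shell_radius, occupancy = sv$occupancy,
      box = unlist(sv$box), bulk_density = sv$bulk_density,
      jitter = sv$jitter, n_frames = sv$n_frames, seed = seed + 3L))
    prof <- rdf(toy, center = 1L, target = seq(2L, n_atoms(toy)),
                bin_width = cfg$solvation$bin_width,
                r_max = cfg$solvation$r_max)
    cn <- coordination_number(prof)
    site <- synthetic_calcium_site()
    mode <- coordination_mode(site, ion = 1L,
                              cutoff = cfg$solvation$coordination_cutoff)
    list(peak_r = prof$r[which.max(prof$g)], cn_first_shell = cn,
         site_cn = mode$cn,
         site_categories = as.list(table(mode$ligands$category)))
  })
  run_stage("cluster", character(0), function() {
    mix <- generate_two_state_ensemble(specs$bound, specs$unbound,
                                       cfg$synthetic$mixture_weight,
                                       n_frames = min(syn$n_frames, 120L),
                                       seed = seed + 4L)
    M <- pairwise_rmsd(mix, sel_all, stride = cfg$cluster$stride)
    cl <- cluster_frames(M, cfg$cluster$cutoff)
    labels <- attr(mix, "labels")[attr(M, "frames")]
    # agreement between clustering and the true mixture labels
    agree <- max(mean((cl$membership == 1) == (labels == 1)),
                 mean((cl$membership == 1) == (labels == 2)))
    repA <- representative_structure(trajs$bound, sel_all,
                                     cfg$cluster$cutoff, cfg$cluster$stride)
    repB <- representative_structure(trajs$unbound, sel_all,
                                     cfg$cluster$cutoff, cfg$cluster$stride)
    cross <- compare_representatives(repA, repB, sel_all)
    list(n_clusters = length(cl$populations), label_agreement = agree,
         cross_state_rmsd = cross)
  })
  run_stage("gbsa", character(0), function() {
    par <- demo_ff_params(N)
    out <- lapply(trajs, function(tr) {
      dec <- binding_energy(tr, receptor = blockA, ligand = blockB, par,
                            frames = seq(1, min(20, n_frames(tr))),
                            solvent_dielectric = cfg$gbsa$solvent_dielectric,
                            solute_dielectric = cfg$gbsa$solute_dielectric,
                            gamma = cfg$gbsa$gamma, b = cfg$gbsa$b,
                            probe = cfg$gbsa$probe,
                            n_points = cfg$gbsa$n_points,
                            offset = cfg$gbsa$offset, scale = cfg$gbsa$scale)
      as.list(setNames(dec$summary$mean, dec$summary$term))
    })
    out$ddG <- out$bound$dG_binding - out$unbound$dG_binding
    out
  })

  report <- structure(list(
    results = results,
    provenance = list(seed = seed, package = "mdensemble",
                      version = as.character(utils::packageVersion("mdensemble")),
                      config = unclass(cfg)),
    warnings = warns,
    errors = errors), class = "analysis_report")
  out_dir <- if (missing(output_dir)) cfg$output_dir else output_dir
  if (!is.null(out_dir) && nzchar(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_payload(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(cfg, file.path(out_dir, "config.yaml"))
  }
  report
}

#' Numeric payload of an analysis report
#'
#' The deterministic part of a report (stage results + seed), used for
#' byte-identical reproducibility checks; provenance that may differ
#' between runs of the same config (timings, paths) is excluded.
#'
#' @param report An `analysis_report`.
#' @return A list safe to serialize and compare across runs.
#' @export
report_payload <- function(report) {
  list(results = report$results, seed = report$provenance$seed,
       warnings = report$warnings)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", length(x$results), "stage blocks; statuses:",
      paste(vapply(x$results, function(b) b$status, character(1)),
            collapse = ", "), "\n")
  if (length(x$errors)) cat("errors in:", paste(names(x$errors),
                                                collapse = ", "), "\n")
  invisible(x)
}
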