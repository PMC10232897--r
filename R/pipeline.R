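# Configuration validation and end-to-end stage orchestration:
# trajectory -> contacts -> RED -> collective variables -> tICA -> MSM
# -> TPT -> coordination analysis, with provenance-stamped CSV outputs.

.configDefaults <- function() list(
  seed = 1L,
  stages = c("contacts", "red", "cv", "tica", "msm", "tpt", "nbit"),
  input = list(),
  contacts = list(cutoff = 3.5, heavyOnly = TRUE, window = 25L),
  red = list(components = 5L, kSigma = 4, cvMax = 0.15, meanMin = 0.5,
             maxIter = 500L),
  cv = list(definitions = NULL, serSite = NULL, trpSite = NULL, dSite = 6.0,
            contactPairs = NULL),
  tica = list(lag = 25L, k = 3L),
  msm = list(k = 200L, lag = 150L, macrostates = 9L,
             timescaleLags = NULL),
  tpt = list(source = 1L, target = 2L, coverage = 0.95),
  nbit = list(motifs = NULL, atoms = "all", mode = "scalar",
              alignResIds = NULL)
)

.mergeConfig <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
                    !k %in% c("input", "motifs", "definitions"))
      .mergeConfig(defaults[[k]], user[[k]], paste0(path, k, "$"))
    else user[[k]]
  }
  out
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults (contact
#' cutoff 3.5 A, smoothing window 25 frames, 5 RED components, SDCP
#' threshold 4 sigma, 200 microstates) and fails hard on unknown keys.
#' The \code{input} section must contain exactly one of
#' \code{synthetic} (a planted-trajectory spec, see
#' [genPlantedTrajectory()]) or \code{files} (topology + trajectories +
#' frameInterval).
#'
#' @param x path to a YAML config or a list.
#' @return validated config list (class "allokinConfig") with a
#'   \code{hash} attribute identifying it
#' @export
validateConfig <- function(x) {
  user <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg <- .mergeConfig(.configDefaults(), user)
  inp <- cfg$input
  if (is.null(inp$synthetic) == is.null(inp$files))
    stop("input must define exactly one of 'synthetic' or 'files'")
  bad <- setdiff(names(inp), c("synthetic", "files"))
  if (length(bad))
    stop("unknown configuration key(s): input$",
         paste(bad, collapse = ", input$"))
  if (!is.null(inp$files)) {
    for (f in c(inp$files$topology, unlist(inp$files$trajectories)))
      if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  cfg$seed <- as.integer(cfg$seed)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  class(cfg) <- c("allokinConfig", "list")
  cfg
}

.writeStamped <- function(df, path, cfg, what) {
  con <- file(path, "w")
  writeLines(c(
    sprintf("# allokin %s | %s", as.character(utils::packageVersion("allokin")),
            what),
    sprintf("# config %s | seed %d", attr(cfg, "hash"), cfg$seed)), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      col.names = TRUE, append = TRUE))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on the configured
#' input and writes provenance-stamped CSV artifacts into \code{outDir}:
#' contact series and pair index, RED temporal weights / events / SDCP
#' table, CV matrix, binding modes, contact probabilities (per binding
#' mode), tICA projections and spectrum, MSM transition matrix /
#' stationary distribution / implied timescales / macrostates, TPT
#' pathway table and the motif coordination matrix. Reruns with the
#' same config reproduce identical outputs.
#'
#' @param cfg a config from [validateConfig()] (or something coercible).
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of the in-memory stage results
#' @export
runPipeline <- function(cfg, outDir) {
  if (!inherits(cfg, "allokinConfig")) cfg <- validateConfig(cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stages <- cfg$stages

  # --- input ---
  if (!is.null(cfg$input$synthetic)) {
    spec <- cfg$input$synthetic
    spec$seed <- spec$seed %||% cfg$seed
    gen <- genPlantedTrajectory(spec)
    traj <- gen$trajectory
    res$truth <- gen$truth
  } else {
    fl <- cfg$input$files
    top <- readStructure(fl$topology)$topology
    traj <- readTrajectory(unlist(fl$trajectories), top,
                           frameInterval = fl$frameInterval %||% NA_real_)
  }
  res$trajectory <- traj
  ligRes <- unique(traj@topology$resId[traj@topology$resName == "LIG"])

  # --- contacts ---
  if (any(c("contacts", "red") %in% stages)) {
    raw <- computeContactSeries(traj, cutoff = cfg$contacts$cutoff,
                                heavyOnly = cfg$contacts$heavyOnly)
    trimmed <- trimInvariantPairs(raw, verbose = FALSE)
    smoothCts <- smoothContacts(trimmed, window = cfg$contacts$window)
    res$contacts <- list(raw = raw, trimmed = trimmed, smooth = smoothCts)
    .writeStamped(pairIndex(smoothCts),
                  file.path(outDir, "pair_index.csv"), cfg, "pair index")
    .writeStamped(as.data.frame(valueMatrix(smoothCts)),
                  file.path(outDir, "contact_series.csv"), cfg,
                  "smoothed contact series")
  }

  # --- RED ---
  if ("red" %in% stages) {
    model <- fitRED(res$contacts$smooth, c = cfg$red$components,
                    maxIter = cfg$red$maxIter)
    constit <- identifyConstitutivePairs(model, cvMax = cfg$red$cvMax,
                                         meanMin = cfg$red$meanMin)
    model <- normalizeComponents(model, constit)
    tl <- dominanceTimeline(model)
    sdcp <- if (nrow(tl$events)) {
      ev <- tl$events[1, ]
      extractSDCPs(model, ev$from, ev$to, kSigma = cfg$red$kSigma)
    } else data.frame()
    res$red <- list(model = model, constitutive = constit,
                    timeline = tl, sdcp = sdcp)
    .writeStamped(as.data.frame(tl$weights),
                  file.path(outDir, "red_temporal.csv"), cfg,
                  "RED temporal weights")
    .writeStamped(tl$events, file.path(outDir, "red_events.csv"), cfg,
                  "RED dominance transition events")
    .writeStamped(sdcp, file.path(outDir, "red_sdcp.csv"), cfg,
                  "structure-differentiating contact pairs")
  }

  # --- collective variables ---
  if (any(c("cv", "tica", "msm", "tpt") %in% stages)) {
    defs <- cfg$cv$definitions
    if (is.null(defs)) {
      if (!length(ligRes) || is.null(cfg$cv$serSite) ||
          is.null(cfg$cv$trpSite))
        stop("cv stage needs explicit definitions, or a ligand plus ",
             "serSite/trpSite residues")
      defs <- list(
        list(name = "lig_ser_dist", type = "com_distance",
             groupA = list(resIds = ligRes),
             groupB = list(resIds = cfg$cv$serSite)),
        list(name = "lig_trp_dist", type = "com_distance",
             groupA = list(resIds = ligRes),
             groupB = list(resIds = cfg$cv$trpSite)))
    }
    cvm <- buildCVMatrix(traj, defs)
    res$cv <- cvm
    .writeStamped(as.data.frame(valueMatrix(cvm)),
                  file.path(outDir, "cv_matrix.csv"), cfg, "CV matrix")
    if (!is.null(cfg$cv$serSite) && !is.null(cfg$cv$trpSite) &&
        length(ligRes)) {
      serD <- comDistance(traj, atomSelection(resIds = ligRes),
                          atomSelection(resIds = cfg$cv$serSite))
      trpD <- comDistance(traj, atomSelection(resIds = ligRes),
                          atomSelection(resIds = cfg$cv$trpSite))
      modes <- classifyBindingMode(serD, trpD, dSite = cfg$cv$dSite)
      res$bindingModes <- modes
      .writeStamped(data.frame(frame = seq_along(modes), mode = modes),
                    file.path(outDir, "binding_modes.csv"), cfg,
                    "binding mode series")
      if (!is.null(cfg$cv$contactPairs)) {
        cp <- do.call(rbind, lapply(cfg$cv$contactPairs, function(p) {
          row <- data.frame(resI = p[[1]], resJ = p[[2]])
          for (lv in levels(modes)) {
            fr <- which(modes == lv)
            row[[paste0("prob", lv)]] <- if (length(fr))
              contactProbability(traj, p[[1]], p[[2]],
                                 cutoff = cfg$contacts$cutoff,
                                 heavyOnly = cfg$contacts$heavyOnly,
                                 frames = fr) else NA_real_
          }
          row
        }))
        res$contactProbability <- cp
        .writeStamped(cp, file.path(outDir, "contact_probability.csv"), cfg,
                      "contact probability (%) per binding mode")
      }
    }
  }

  # --- tICA ---
  if (any(c("tica", "msm", "tpt") %in% stages)) {
    tic <- fitTICA(res$cv, lag = cfg$tica$lag)
    proj <- projectTICA(tic, res$cv, k = cfg$tica$k)
    res$tica <- list(model = tic, projections = proj)
    .writeStamped(data.frame(index = seq_along(tic@eigenvalues),
                             eigenvalue = tic@eigenvalues,
                             kineticContent = vapply(
                               seq_along(tic@eigenvalues),
                               function(k) kineticContent(tic, k),
                               numeric(1))),
                  file.path(outDir, "tica_eigen.csv"), cfg, "tICA spectrum")
    .writeStamped(as.data.frame(proj),
                  file.path(outDir, "tica_projections.csv"), cfg,
                  "tICA projections")
  }

  # --- MSM ---
  if (any(c("msm", "tpt") %in% stages)) {
    projSegs <- splitSegments(res$tica$projections, segmentStarts(res$cv))
    micro <- clusterMicrostates(projSegs, k = cfg$msm$k, seed = cfg$seed)
    micro <- buildTPM(micro, lag = cfg$msm$lag)
    macro <- pccaMacrostates(micro, m = cfg$msm$macrostates)
    lagList <- cfg$msm$timescaleLags %||%
      unique(pmax(1L, as.integer(round(cfg$msm$lag * c(0.5, 1, 2)))))
    its <- impliedTimescales(micro@assignments, lagList)
    res$msm <- list(micro = micro, macro = macro, timescales = its)
    .writeStamped(as.data.frame(transitionMatrix(micro)),
                  file.path(outDir, "msm_tpm.csv"), cfg,
                  "symmetrized transition probability matrix")
    .writeStamped(data.frame(state = micro@active,
                             pi = stationaryDistribution(micro),
                             macrostate = macro@crisp),
                  file.path(outDir, "msm_states.csv"), cfg,
                  "stationary distribution and macrostate map")
    .writeStamped(its, file.path(outDir, "implied_timescales.csv"), cfg,
                  "implied timescale test")
    .writeStamped(data.frame(macrostate = seq_along(macro@populations),
                             population = macro@populations),
                  file.path(outDir, "macrostate_populations.csv"), cfg,
                  "macrostate populations")
  }

  # --- TPT ---
  if ("tpt" %in% stages) {
    macro <- res$msm$macro
    srcMicro <- which(macro@crisp == cfg$tpt$source)
    dstMicro <- which(macro@crisp == cfg$tpt$target)
    if (!length(srcMicro) || !length(dstMicro))
      stop("empty source or target macrostate for TPT")
    fx <- transitionPaths(res$msm$micro, srcMicro, dstMicro,
                          coverage = cfg$tpt$coverage)
    res$tpt <- fx
    .writeStamped(data.frame(Path = fx@pathways$path,
                             NormFlux = round(fx@pathways$normFlux, 4),
                             CumulativeFlux = round(fx@pathways$cumFlux, 4)),
                  file.path(outDir, "tpt_pathways.csv"), cfg,
                  "pathway decomposition of the net flux")
  }

  # --- coordination (NbIT) ---
  if ("nbit" %in% stages) {
    motifs <- cfg$nbit$motifs
    if (is.null(motifs))
      stop("nbit stage needs a named list of motifs (residue id vectors)")
    alignRes <- cfg$nbit$alignResIds %||%
      setdiff(unique(traj@topology$resId), ligRes)
    ref <- traj
    ref@coords <- traj@coords[1, , , drop = FALSE]
    sel <- atomSelection(resIds = alignRes,
                         atomNames = if (cfg$nbit$atoms == "ca") "CA"
                                     else character())
    aligned <- superpose(traj, ref, sel)
    ens <- lapply(motifs, function(rr)
      displacementEnsemble(aligned, rr, ref, mode = cfg$nbit$mode,
                           atoms = cfg$nbit$atoms))
    for (i in seq_along(ens)) ens[[i]]@motif <- names(motifs)[i]
    cm <- coordinationMatrix(ens)
    res$nbit <- list(ensembles = ens, matrix = cm)
    out <- data.frame(receiver = rownames(valueMatrix(cm)),
                      round(valueMatrix(cm), 3), check.names = FALSE)
    .writeStamped(out, file.path(outDir, "coordination_matrix.csv"), cfg,
                  "TC (nats, diagonal) and NCI (%, off-diagonal)")
  }

  info <- list(package = "allokin",
               version = as.character(utils::packageVersion("allokin")),
               configHash = attr(cfg, "hash"), seed = cfg$seed,
               stages = stages)
  yaml::write_yaml(info, file.path(outDir, "run_info.yaml"))
  invisible(res)
}
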