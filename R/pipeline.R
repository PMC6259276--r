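## cli_reports: end-to-end orchestration and report tables.

#' Default pipeline configuration
#'
#' Defaults follow the standard settings of the reference analysis: 1 A grid
#' spacing, 4 A margin, sp3 carbon probe of charge +1e (CoMSIA radius 1 A),
#' attenuation factor 0.3, column filter 2.0, leave-one-out CV with block
#' scaling, template compound 10.
#'
#' @param ... overrides for individual entries.
#' @return named list of settings.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    spacing = 1.0, margin = 4.0,
    probeCharge = 1.0, probeRadius = 1.0,
    alpha = 0.3, cutoff = 30,
    filterThreshold = 2.0,
    filterOn = "scaled",       # minimum-sigma applied after block scaling
                               # ("raw": filter the unscaled columns)
    maxComponents = 10L,
    scaling = "comfa_std",
    templateId = "10",
    seed = 1L,
    contourFavoredPct = 80, contourDisfavoredPct = 20,
    outputDir = NULL)
  ovr <- list(...)
  bad <- setdiff(names(ovr), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ovr)] <- ovr
  cfg
}

.comfaChannels <- c("comfa_steric", "comfa_elec")
.comsiaChannels <- c("comsia_steric", "comsia_elec", "comsia_hydrophobic",
                     "comsia_donor", "comsia_acceptor")

# column mask honouring the filterOn mode
.maskFor <- function(vals, chcol, cfg) {
  if (identical(cfg$filterOn, "scaled")) {
    w <- .columnWeights(sweep(vals, 2, colMeans(vals)), cfg$scaling, chcol)
    filterColumns(sweep(vals, 2, w, "*"), cfg$filterThreshold)
  } else {
    filterColumns(vals, cfg$filterThreshold)
  }
}

# fit + cross-validate + validate one model on a channel subset
.fitOneModel <- function(fm, chans, tab, cfg) {
  sub <- fieldSubset(fm, chans)
  vals <- fieldValues(sub)
  chcol <- channelOfColumn(sub)
  train <- tab$subset == "train"
  ytr <- tab$pec50[train]
  mask <- .maskFor(vals[train, , drop = FALSE], chcol, cfg)
  loo <- looCrossValidate(vals[train, , drop = FALSE], ytr,
    maxComponents = cfg$maxComponents, scaling = cfg$scaling,
    mask = mask, channelOfColumn = chcol)
  model <- fitPLS(vals[train, , drop = FALSE], ytr, ncomp = onc(loo),
    scaling = cfg$scaling, mask = mask, channelOfColumn = chcol)
  stats <- internalStats(model, vals[train, , drop = FALSE], ytr)
  predAll <- predict(model, vals)
  ext <- externalValidation(tab$pec50[!train], predAll[!train],
    trainMean = mean(ytr), trainR2 = stats$r2, q2 = q2(loo)[onc(loo)])
  trainFM <- new("FieldMatrix", values = vals[train, , drop = FALSE],
    channels = channels(sub), grid = sub@grid,
    compoundIds = sub@compoundIds[train])
  contours <- lapply(channels(sub), function(ch)
    stdevCoeffField(model, trainFM, ch))
  names(contours) <- channels(sub)
  list(model = model, loo = loo, internal = stats, external = ext,
       predictions = predAll, contours = contours)
}

#' Run the full 3D-QSAR pipeline
#'
#' Executes structure construction, 3D embedding + charging, template
#' alignment, field evaluation, PLS fitting with LOO component selection for
#' both field models (CoMFA on the two energy channels, CoMSIA on the five
#' similarity channels), external validation on the held-out test compounds,
#' and contour-field generation. When \code{config$outputDir} is set, the
#' report tables (\code{table2_like.csv}, \code{table3_like.json},
#' \code{table4_like.json}), contour grids (OpenDX), alignment sidecar and a
#' run log are written there.
#'
#' @param config a \code{\link{defaultConfig}} list.
#' @param compounds compound table (defaults to the packaged series).
#' @return (invisibly) list with conformers, alignment, the
#'   \code{\link{FieldMatrix}}, per-model fit/validation results, the report
#'   tables, and the run log.
#' @export
runPipeline <- function(config = defaultConfig(), compounds = compoundTable()) {
  log <- character(0)
  tick <- function(stage, t0) {
    msg <- sprintf("%s: %.1f s (seed %d)", stage,
                   as.numeric(Sys.time()) - t0, config$seed)
    message(msg)
    log <<- c(log, msg)
  }
  t0 <- as.numeric(Sys.time())
  smiles <- compoundSmilesTable(compounds)
  confs <- embedConformers(smiles, seed = config$seed)
  tick("structure_prep", t0)

  t0 <- as.numeric(Sys.time())
  ali <- alignSet(confs, templateId = config$templateId)
  tick("alignment", t0)

  t0 <- as.numeric(Sys.time())
  grid <- makeGrid(ali$conformers, spacing = config$spacing,
                   margin = config$margin)
  probe <- probeSpec(charge = config$probeCharge, radius = config$probeRadius)
  fm <- assembleFieldMatrix(ali$conformers, grid, probe,
    cutoff = config$cutoff, alpha = config$alpha)
  tick("grid_fields", t0)

  t0 <- as.numeric(Sys.time())
  comfa <- .fitOneModel(fm, .comfaChannels, compounds, config)
  comsia <- .fitOneModel(fm, .comsiaChannels, compounds, config)
  tick("pls_and_validation", t0)

  tables <- reportTables(compounds, comfa, comsia)
  out <- list(config = config, conformers = ali$conformers,
    alignment = ali$results, fieldMatrix = fm,
    comfa = comfa, comsia = comsia, tables = tables, log = log)
  if (!is.null(config$outputDir)) writeRunArtifacts(out, config$outputDir)
  invisible(out)
}

# assemble the three report tables from two fitted models
reportTables <- function(tab, comfa, comsia) {
  t2 <- data.frame(id = tab$id, pec50_actual = tab$pec50,
    pred_comfa = comfa$predictions,
    res_comfa = tab$pec50 - comfa$predictions,
    pred_comsia = comsia$predictions,
    res_comsia = tab$pec50 - comsia$predictions,
    subset = tab$subset)
  t3 <- lapply(list(comfa = comfa, comsia = comsia), function(m)
    list(r2cv = unname(q2(m$loo)[onc(m$loo)]), onc = onc(m$loo),
      r2 = m$internal$r2, see = m$internal$see, f = m$internal$f,
      contributions = as.list(m$internal$contributions)))
  t4 <- lapply(list(comfa = comfa, comsia = comsia), function(m)
    m$external[c("r2pred", "k", "kPrime", "r0sq", "r0sqPrime",
                 "rm2", "ratio")])
  list(table2 = t2, table3 = t3, table4 = t4)
}

writeRunArtifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$tables$table2, file.path(dir, "table2_like.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$tables$table3, file.path(dir, "table3_like.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(run$tables$table4, file.path(dir, "table4_like.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeAlignmentJSON(run$alignment, file.path(dir, "alignment.json"))
  for (m in c("comfa", "comsia"))
    for (ch in names(run[[m]]$contours))
      writeOpenDX(run[[m]]$contours[[ch]],
                  file.path(dir, paste0("contour_", ch, ".dx")))
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Statistics-only report from a packaged prediction table
#'
#' Recomputes the internal and external validation statistics of both field
#' models directly from an actual/predicted activity table, without any
#' structure or field computation. Internal statistics use the component
#' count of the published analysis (from \code{\link{publishedModelStats}}).
#' The report also carries the derived reference quantities obtained from
#' the published summary constants themselves: rm^2 and the (r2 - r0^2)/r2
#' gap ratio of each model.
#'
#' @param activity table from \code{\link{activityTable}}.
#' @param published table from \code{\link{publishedModelStats}}.
#' @return nested list: per model, \code{internal} (r2, see, f, ncomp),
#'   \code{external} (see \code{\link{externalValidation}}), and
#'   \code{reference} (rm2 and ratio from the published constants).
#' @export
statsOnlyReport <- function(activity = activityTable(),
                            published = publishedModelStats()) {
  pub <- function(m, s) published$value[published$model == m &
                                        published$statistic == s]
  train <- activity$subset == "train"
  out <- lapply(c(comfa = "comfa", comsia = "comsia"), function(m) {
    y <- activity$pec50_actual
    p <- activity[[paste0("pred_", m)]]
    ytr <- y[train]; ptr <- p[train]
    n <- sum(train); c <- as.integer(pub(m, "onc"))
    ssres <- sum((ytr - ptr)^2)
    sstot <- sum((ytr - mean(ytr))^2)
    r2 <- 1 - ssres / sstot
    internal <- list(r2 = r2, see = sqrt(ssres / (n - c - 1)),
      f = (r2 / c) / ((1 - r2) / (n - c - 1)), ncomp = c)
    external <- externalValidation(y[!train], p[!train],
      trainMean = mean(ytr), trainR2 = r2, q2 = pub(m, "r2cv"))
    reference <- list(
      rm2 = rmSquared(pub(m, "r2"), pub(m, "r0sq")),
      ratio = (pub(m, "r2") - pub(m, "r0sq")) / pub(m, "r2"))
    list(internal = internal, external = external, reference = reference)
  })
  out
}
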