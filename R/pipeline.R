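# Workflow wiring: variant-table and model (de)serialization and the
# subcommand front-end used by the thin command-line script.

#' Read / write a variant table
#'
#' Tab-separated variant tables with columns pdb_id, chain, resno, wt_aa,
#' mut_aa and optionally label and provean-style score; internal column
#' names (wt, mut, pro) are mapped on the way in and out.
#'
#' @param file path.
#' @param variants data.frame.
#' @return data.frame / invisible path.
#' @export
readVariantTable <- function(file) {
  v <- utils::read.delim(file, stringsAsFactors = FALSE)
  ren <- c(wt_aa = "wt", mut_aa = "mut", provean = "pro")
  for (k in names(ren))
    if (k %in% names(v)) names(v)[names(v) == k] <- ren[[k]]
  if (!"protein" %in% names(v) && "pdb_id" %in% names(v))
    v$protein <- v$pdb_id
  if ("label" %in% names(v) && !"isDel" %in% names(v))
    v$isDel <- v$label == "deleterious"
  if ("ins" %in% names(v)) v$ins[is.na(v$ins)] <- ""
  v
}

#' @rdname readVariantTable
#' @export
writeVariantTable <- function(variants, file) {
  utils::write.table(variants, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

.modelToList <- function(m) {
  if (is(m, "AnnModel"))
    list(class = "AnnModel", gates = as.list(as.data.frame(m@gates)),
         subset = m@subset, potentialNames = m@potentialNames,
         threshold = m@threshold, trainMse = m@trainMse)
  else if (is(m, "GatedLinearModel"))
    list(class = "GatedLinearModel",
         gates = as.list(as.data.frame(m@gates)), terms = m@terms,
         kind = m@kind, sizeScaling = m@sizeScaling, trainMse = m@trainMse)
  else if (is(m, "PnnModel"))
    list(class = "PnnModel", X = as.data.frame(m@X), isDel = m@isDel,
         sigma = m@sigma, eta = m@eta, featureNames = m@featureNames,
         looBacc = m@looBacc)
  else if (is(m, "CombinerModel"))
    list(class = "CombinerModel", gamma = m@gamma, threshold = m@threshold,
         jD = m@jD, jN = m@jN, trainBacc = m@trainBacc)
  else stop("unsupported model class: ", class(m))
}

.gatesFromList <- function(g, terms) {
  gm <- do.call(cbind, lapply(g, unlist))
  rownames(gm) <- c("omega", "nu", "xi", "phi")
  colnames(gm) <- terms
  gm
}

#' Serialize / read a model
#'
#' Versioned JSON documents for every model class; the run provenance
#' (configuration hash and seed) is embedded alongside the parameters.
#'
#' @param m model object.
#' @param file path.
#' @param provenance optional list stored verbatim (e.g. from
#'   [runProvenance()]).
#' @return `writeModel`: invisible path; `readModel`: the model.
#' @export
writeModel <- function(m, file, provenance = NULL) {
  doc <- c(list(format_version = 1L), .modelToList(m),
           list(provenance = provenance))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeModel
#' @export
readModel <- function(file) {
  d <- jsonlite::read_json(file, simplifyVector = TRUE)
  switch(d$class,
    AnnModel = new("AnnModel",
      gates = .gatesFromList(d$gates,
                             c(paste0("pos.", d$potentialNames),
                               paste0("neg.", d$potentialNames),
                               "dVp", "dVm")),
      subset = as.integer(d$subset), potentialNames = d$potentialNames,
      threshold = d$threshold, trainMse = d$trainMse),
    GatedLinearModel = new("GatedLinearModel",
      gates = .gatesFromList(d$gates, d$terms), terms = d$terms,
      kind = d$kind, sizeScaling = d$sizeScaling, trainMse = d$trainMse),
    PnnModel = new("PnnModel", X = as.matrix(d$X), isDel = d$isDel,
      sigma = d$sigma, eta = d$eta, featureNames = d$featureNames,
      looBacc = d$looBacc),
    CombinerModel = new("CombinerModel", gamma = d$gamma,
      threshold = d$threshold, jD = d$jD, jN = d$jN,
      trainBacc = d$trainBacc),
    stop("unsupported model class in file: ", d$class)
  )
}

#' Run provenance block
#'
#' Configuration hash and root seed embedded in every artifact a pipeline
#' run writes.
#'
#' @param config configuration list.
#' @param seed integer seed.
#' @return list(config_hash, seed).
#' @export
runProvenance <- function(config, seed) {
  list(config_hash = rlang::hash(config), seed = as.integer(seed))
}

.parseArgs <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1], "--"))
      stop("missing value for --", key)
    out[[key]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

.loadStructuresDir <- function(dir, config) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  if (!length(files)) stop("no PDB files in ", dir)
  structs <- lapply(files, function(f)
    computeDescriptors(readStructure(f), config))
  names(structs) <- vapply(structs, function(s) s@pdbId, character(1))
  structs
}

.loadPotentialsDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.pot\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no potential tables in ", dir)
  tabs <- lapply(files, readPotentialTable)
  names(tabs) <- vapply(tabs, function(t) t@name, character(1))
  tabs
}

#' Command-line pipeline entry point
#'
#' Thin subcommand front-end over the package functions:
#' \describe{
#'   \item{make-fixtures}{`--out DIR [--n 4 --length 40 --geometry mixed
#'     --seed 1 --variants N]`: writes synthetic PDB files and, with
#'     `--variants`, derives potentials from them and writes a labeled
#'     variant table plus the potential tables.}
#'   \item{derive-potentials}{`--structures DIR --out DIR [--config YML]`.}
#'   \item{train-ann / train-pnn / train-combiner}{`--variants TSV
#'     --structures DIR --potentials DIR --out model.json [--seed N]`.}
#'   \item{predict}{`--variants TSV --structures DIR --potentials DIR
#'     --model model.json --out TSV`: appends index, call and confidence
#'     band columns.}
#'   \item{evaluate}{`--variants TSV --structures DIR --potentials DIR
#'     --out report.json [--classifier ann|pnn|combiner|accessibility
#'     --level mutation|protein --k 5 --seed N]`.}
#' }
#' All artifacts embed the configuration hash and seed. Errors print to
#' stderr and yield a nonzero status.
#'
#' @param argv character vector: subcommand followed by --key value pairs.
#' @return integer exit status (0 on success), invisibly.
#' @export
runPipeline <- function(argv) {
  status <- tryCatch({
    if (!length(argv)) stop("no subcommand given")
    cmd <- argv[1]
    args <- .parseArgs(argv[-1])
    config <- loadConfig(args$config)
    seed <- as.integer(args$seed %||% 1L)
    prov <- runProvenance(config, seed)
    num <- function(x, d) if (is.null(x)) d else as.numeric(x)

    if (cmd == "make-fixtures") {
      if (is.null(args$out)) stop("--out required")
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      docs <- makeStructures(
        nStructures = num(args$n, 4), chainLength = num(args$length, 40),
        geometry = args$geometry %||% "mixed", seed = seed)
      for (id in names(docs))
        writeLines(docs[[id]], file.path(args$out, paste0(id, ".pdb")))
      if (!is.null(args$variants)) {
        structs <- .loadStructuresDir(args$out, config)
        tabs <- derivePotentials(structs, config)
        for (nm in names(tabs))
          writePotentialTable(tabs[[nm]],
                              file.path(args$out, paste0(nm, ".pot.tsv")))
        vt <- makeVariantTable(structs, tabs,
                               nVariants = as.integer(args$variants),
                               config = config, seed = seed)
        writeVariantTable(vt, file.path(args$out, "variants.tsv"))
      }
      message("fixtures written to ", args$out)
    } else if (cmd == "derive-potentials") {
      structs <- .loadStructuresDir(args$structures, config)
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      tabs <- derivePotentials(structs, config)
      for (nm in names(tabs))
        writePotentialTable(tabs[[nm]],
                            file.path(args$out, paste0(nm, ".pot.tsv")))
      message(length(tabs), " potential tables written to ", args$out)
    } else if (cmd %in% c("train-ann", "train-pnn", "train-combiner")) {
      v <- readVariantTable(args$variants)
      structs <- .loadStructuresDir(args$structures, config)
      tabs <- .loadPotentialsDir(args$potentials)
      feats <- if (any(grepl("^ddW\\.", names(v)))) v
               else featurizeVariants(structs, v, tabs, config)
      m <- switch(cmd,
        `train-ann` = trainAnn(feats, feats$isDel, config, seed = seed),
        `train-pnn` = trainPnn(feats, feats$isDel, config, seed = seed),
        `train-combiner` = {
          ann <- trainAnn(feats, feats$isDel, config, seed = seed)
          trainCombiner(annIndex(ann, feats, config), feats$pro,
                        feats$isDel, seed = seed)
        })
      writeModel(m, args$out, provenance = prov)
      message("model written to ", args$out)
    } else if (cmd == "predict") {
      v <- readVariantTable(args$variants)
      structs <- .loadStructuresDir(args$structures, config)
      tabs <- .loadPotentialsDir(args$potentials)
      feats <- featurizeVariants(structs, v, tabs, config)
      m <- readModel(args$model)
      if (is(m, "AnnModel")) {
        feats$I <- annIndex(m, feats, config)
        feats$call <- classifyByThreshold(feats$I, m@threshold, "higher")
      } else if (is(m, "PnnModel")) {
        cl <- pnnClassify(m, feats, config)
        feats$PD <- cl$PD; feats$PN <- cl$PN; feats$call <- cl$call
      } else if (is(m, "CombinerModel")) {
        stop("predict with a combiner model needs the index column; ",
             "run predict with the gated-index model first")
      }
      writeVariantTable(feats, args$out)
      message("predictions written to ", args$out)
    } else if (cmd == "evaluate") {
      v <- readVariantTable(args$variants)
      structs <- .loadStructuresDir(args$structures, config)
      tabs <- .loadPotentialsDir(args$potentials)
      feats <- if (any(grepl("^ddW\\.", names(v)))) v
               else featurizeVariants(structs, v, tabs, config)
      trainer <- switch(args$classifier %||% "ann",
                        ann = annTrainer(config),
                        pnn = pnnTrainer(config),
                        combiner = combinerTrainer(config),
                        accessibility = accessibilityTrainer(config),
                        stop("unknown classifier: ", args$classifier))
      rep <- crossValidate(trainer, feats, k = num(args$k, 5),
                           level = args$level %||% "mutation", seed = seed)
      doc <- list(summary = as.list(rep@summary),
                  auroc_pooled = rep@aurocPooled,
                  per_fold = rep@perFold, level = rep@level,
                  provenance = prov)
      jsonlite::write_json(doc, args$out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      message("evaluation report written to ", args$out)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
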