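#' @importFrom utils read.delim write.table head
NULL

# File dialect used throughout: tab-separated, UTF-8, mandatory header
# row, '#' lines are comments.

.readTSV <- function(path, ...) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE,
               fileEncoding = "UTF-8", ...)
}

.writeTSV <- function(df, path, rowLabel = NULL) {
    if (!is.null(rowLabel))
        df <- cbind(stats::setNames(data.frame(rownames(df)), rowLabel), df)
    ok <- tryCatch({
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    fileEncoding = "UTF-8")
        TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
                                conditionMessage(e)))
    invisible(ok)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of gene labels and a first column of neuron
#' labels; the numeric body must be complete and nonnegative. The neuron
#' order in this file is the canonical order for all derived matrices.
#'
#' @param path TSV file path
#' @return an [ExpressionMatrix-class]
#' @export
readExpression <- function(path) {
    df <- .readTSV(path)
    if (nrow(df) == 0L) stop("empty expression table: ", path)
    labels <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
    m <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    m <- matrix(m, nrow = nrow(body),
                dimnames = list(labels, colnames(body)))
    if (anyNA(m)) stop("malformed or missing numeric value in ", path)
    message(sprintf("read %d neurons x %d genes from %s",
                    nrow(m), ncol(m), basename(path)))
    ExpressionMatrix(m)
}

#' Write an expression matrix to TSV
#'
#' @param x an [ExpressionMatrix-class]
#' @param path output file path
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "ExpressionMatrix"))
    .writeTSV(as.data.frame(exprValues(x)), path, rowLabel = "neuron")
}

#' Read a wiring-rule network from TSV
#'
#' Header row of receptor labels, first column of NT labels.
#'
#' @param path TSV file path
#' @param ternary whether entries must be in \{-1, 0, +1\}
#' @return a [WiringRuleNetwork-class]
#' @export
readRules <- function(path, ternary = TRUE) {
    df <- .readTSV(path)
    if (nrow(df) == 0L) stop("empty rule table: ", path)
    labels <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
    m <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
    m <- matrix(m, nrow = nrow(body), dimnames = list(labels, colnames(body)))
    if (anyNA(m)) stop("malformed or missing numeric value in ", path)
    WiringRuleNetwork(m, ternary = ternary)
}

#' Write a wiring-rule network to TSV
#'
#' @param O a [WiringRuleNetwork-class]
#' @param path output file path
#' @export
writeRules <- function(O, path) {
    stopifnot(is(O, "WiringRuleNetwork"))
    .writeTSV(as.data.frame(ruleWeights(O)), path, rowLabel = "nt")
}

#' Read a signed edge list
#'
#' TSV with columns `pre`, `post`, `category`, `sign`; `sign` must be
#' empty (or 0) except on known-polarity rows, where it must match the
#' category. Edges may appear in any order; the canonical neuron order
#' is supplied by `neuronIds` (normally from the expression file).
#'
#' @param path TSV file path
#' @param neuronIds canonical neuron label order
#' @return list with `connectome` ([SignedConnectome-class]), `mask`
#'   ([ConnectomeMask-class]) and `catalog` ([PolarityCatalog-class]),
#'   mutually consistent
#' @export
readSignedEdges <- function(path, neuronIds) {
    df <- .readTSV(path, colClasses = "character")
    need <- c("pre", "post", "category", "sign")
    if (!all(need %in% names(df)))
        stop("edge list needs columns ", paste(need, collapse = ", "))
    df$sign[is.na(df$sign) | df$sign == ""] <- "0"
    sgn <- suppressWarnings(as.numeric(df$sign))
    if (anyNA(sgn)) stop("malformed sign value in ", path)
    bad <- !df$pre %in% neuronIds | !df$post %in% neuronIds
    if (any(bad))
        stop("unknown neuron label(s): ",
             paste(head(unique(c(df$pre[bad], df$post[bad]))), collapse = ", "))
    if (anyDuplicated(paste(df$pre, df$post, sep = "\r")))
        stop("duplicate directed edge in ", path)
    known <- df$category %in% c("known_positive", "known_negative")
    if (any(sgn[!known] != 0))
        stop("sign given for a non-known category in ", path)
    want <- ifelse(df$category == "known_positive", 1,
                   ifelse(df$category == "known_negative", -1, 0))
    if (any(sgn[known] != want[known]))
        stop("sign does not match known category in ", path)

    n <- length(neuronIds)
    signs <- matrix(0, n, n, dimnames = list(neuronIds, neuronIds))
    present <- matrix(0, n, n, dimnames = list(neuronIds, neuronIds))
    ij <- cbind(match(df$pre, neuronIds), match(df$post, neuronIds))
    present[ij] <- 1
    signs[ij] <- sgn
    catalog <- PolarityCatalog(
        data.frame(pre = df$pre, post = df$post, category = df$category,
                   sign = sgn, stringsAsFactors = FALSE),
        neuronIds = neuronIds)
    message(sprintf("read %d directed edges (%d known) from %s",
                    nrow(df), sum(known), basename(path)))
    list(connectome = SignedConnectome(signs),
         mask = ConnectomeMask(present), catalog = catalog)
}

#' Write a polarity catalog as a signed edge list
#'
#' @param catalog a [PolarityCatalog-class]
#' @param path output file path
#' @export
writeSignedEdges <- function(catalog, path) {
    stopifnot(is(catalog, "PolarityCatalog"))
    df <- catalogTable(catalog)
    df$sign <- ifelse(df$sign == 0, "", as.character(df$sign))
    .writeTSV(df, path)
}

#' Write ranked predictions to TSV
#'
#' Columns `rank`, `pre`, `post`, `score`, `sign`; an empty prediction
#' set produces a header-only file.
#'
#' @param ranked a [RankedPredictions-class]
#' @param path output file path
#' @export
writePredictions <- function(ranked, path) {
    stopifnot(is(ranked, "RankedPredictions"))
    .writeTSV(predTable(ranked), path)
}

#' Read ranked predictions from TSV
#'
#' @param path file written by [writePredictions()]
#' @param method method tag to attach
#' @return a [RankedPredictions-class]
#' @export
readPredictions <- function(path, method = "score") {
    df <- .readTSV(path)
    need <- c("rank", "pre", "post", "score", "sign")
    if (!all(need %in% names(df)))
        stop("prediction table needs columns ", paste(need, collapse = ", "))
    df$pre <- as.character(df$pre); df$post <- as.character(df$post)
    .newRanked(df[, need], method)
}

#' Export a signed network to GraphML
#'
#' Edges carry a `sign` attribute and, when scores are supplied, a
#' `score` attribute.
#'
#' @param A a [SignedConnectome-class]
#' @param path output .graphml path
#' @param scores optional [ScoreMatrix-class] with matching neuron order
#' @export
writeGraphML <- function(A, path, scores = NULL) {
    stopifnot(is(A, "SignedConnectome"))
    s <- signMatrix(A)
    idx <- which(s != 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(s)[idx[, 1]],
                        to = colnames(s)[idx[, 2]],
                        sign = s[idx])
    if (!is.null(scores))
        edges$score <- scoreValues(scores)[idx]
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = rownames(s))
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Write a full synthetic dataset bundle
#'
#' Writes `X.tsv`, `Y.tsv`, `O.tsv`, `edges.tsv` and a `metadata.yaml`
#' embedding the generating model parameters and seed, so any run can be
#' reproduced from its artifacts alone.
#'
#' @param data list from [generatePlanted()]
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
writeDatasetBundle <- function(data, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpression(data$X, file.path(dir, "X.tsv"))
    writeExpression(data$Y, file.path(dir, "Y.tsv"))
    writeRules(data$O, file.path(dir, "O.tsv"))
    writeSignedEdges(data$catalog, file.path(dir, "edges.tsv"))
    m <- data$model
    meta <- list(nNeurons = m@nNeurons, nNT = m@nNT, nR = m@nR,
                 pExpressNT = m@pExpressNT, pExpressR = m@pExpressR,
                 ruleDensity = m@ruleDensity, pRulePositive = m@pRulePositive,
                 edgeDensity = m@edgeDensity, hideFraction = m@hideFraction,
                 labelNoise = m@labelNoise, seed = m@seed)
    yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
    invisible(dir)
}

#' Load a deposited polarity dataset through a configurable adapter
#'
#' Maps an external deposit (e.g. the curated *C. elegans* expression /
#' wiring-rule / connectome tables) onto the package's TSV schemas. The
#' deposit's internal layout is not standardized, so the mapping is
#' configured, not hard-coded: `config` (a list or a YAML file path)
#' names the four files and, for the edge list, the column mapping and a
#' translation of its category vocabulary.
#'
#' @param dir directory holding the deposit files
#' @param config list or YAML path with entries `files` (named `X`, `Y`,
#'   `O`, `edges`) and optionally `columns` (mapping of `pre`, `post`,
#'   `category`, `sign` to the deposit's column names) and `categories`
#'   (named translation to the package vocabulary)
#' @return list as from [readSignedEdges()], plus `X`, `Y`, `O`
#' @export
loadPolarityDataset <- function(dir, config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    f <- function(nm) file.path(dir, config$files[[nm]])
    X <- readExpression(f("X"))
    Y <- readExpression(f("Y"))
    O <- readRules(f("O"))
    edgesPath <- f("edges")
    cols <- config$columns
    if (!is.null(cols) || !is.null(config$categories)) {
        df <- .readTSV(edgesPath, colClasses = "character")
        if (!is.null(cols))
            for (nm in names(cols)) names(df)[names(df) == cols[[nm]]] <- nm
        if (!is.null(config$categories))
            df$category <- vapply(df$category, function(x)
                config$categories[[x]] %||% x, "")
        edgesPath <- tempfile(fileext = ".tsv")
        .writeTSV(df, edgesPath)
        on.exit(unlink(edgesPath))
    }
    out <- readSignedEdges(edgesPath, neuronIds = neuronIds(X))
    c(out, list(X = X, Y = Y, O = O))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
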