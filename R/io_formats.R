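#' Landmark table dialect
#'
#' Describes the on-disk layout of a landmark table so that
#' [read_landmark_table()] never has to sniff. Two layouts are supported:
#' `"wide"` (one row per leaf, coordinate columns `x1..x15, y1..y15`) and
#' `"long"` (one row per landmark, columns for leaf id, landmark index, x, y).
#'
#' @param layout `"wide"` or `"long"`.
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @param id_col,species_col,class_col,vine_col,node_col Metadata column
#'   names. `class_col`, `species_col`, `vine_col` and `node_col` may be `NA`
#'   if the file lacks them.
#' @param landmark_col,x_col,y_col Long-layout column names (ignored for
#'   wide).
#' @param node_numbering `"base1"` if the node column already counts from the
#'   shoot base, `"tip1"` if it counts from the growing tip (converted at
#'   ingest via [convert_node_numbering()], which needs `nodes_on_vine` --
#'   inferred as the maximum node per vine).
#' @return A `landmark_dialect` list.
#' @export
landmark_dialect <- function(layout = c("wide", "long"), sep = ",",
                             id_col = "leaf_id", species_col = "species",
                             class_col = "class", vine_col = "vine",
                             node_col = "node",
                             landmark_col = "landmark", x_col = "x",
                             y_col = "y",
                             node_numbering = c("base1", "tip1")) {
  layout <- match.arg(layout)
  node_numbering <- match.arg(node_numbering)
  structure(list(layout = layout, sep = sep, id_col = id_col,
                 species_col = species_col, class_col = class_col,
                 vine_col = vine_col, node_col = node_col,
                 landmark_col = landmark_col, x_col = x_col, y_col = y_col,
                 node_numbering = node_numbering),
            class = "landmark_dialect")
}

N_LANDMARKS <- 15L

#' Construct a landmark table
#'
#' The central container pairing per-leaf metadata with 15-landmark
#' configurations. Coordinates are stored as a `15 x 2 x n` array in the
#' standard morphometric convention (landmarks x dimensions x specimens).
#'
#' @param coords Numeric array `15 x 2 x n` (or a single `15 x 2` matrix).
#' @param records Data frame with one row per leaf; must contain `leaf_id`.
#'   Conventional columns: `species`, `class`, `vine`, `node` (base-1 at the
#'   shoot base).
#' @return A `landmark_table`.
#' @export
landmark_table <- function(coords, records) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 2L, 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  if (dim(coords)[1] != N_LANDMARKS || dim(coords)[2] != 2L)
    stop("coords must be ", N_LANDMARKS, " x 2 x n")
  if (!all(is.finite(coords)))
    stop("non-finite landmark coordinates")
  records <- as.data.frame(records)
  if (!"leaf_id" %in% names(records)) stop("records must have a leaf_id column")
  if (nrow(records) != dim(coords)[3])
    stop("records (", nrow(records), ") and configurations (",
         dim(coords)[3], ") differ in length")
  dimnames(coords) <- list(NULL, c("x", "y"), records$leaf_id)
  structure(list(coords = coords, records = records), class = "landmark_table")
}

#' @export
print.landmark_table <- function(x, ...) {
  cat("landmark_table:", dim(x$coords)[3], "leaves x", dim(x$coords)[1],
      "landmarks\n")
  if ("species" %in% names(x$records))
    cat("  species:", length(unique(x$records$species)), "\n")
  invisible(x)
}

#' @export
length.landmark_table <- function(x) dim(x$coords)[3]

#' Read a landmark table from disk
#'
#' @param path File path.
#' @param dialect A [landmark_dialect()].
#' @return A [landmark_table()]. Leaves with missing (non-finite) landmarks
#'   are dropped with a warning naming them.
#' @export
read_landmark_table <- function(path, dialect = landmark_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect$layout == "wide") {
    xy <- paste0(rep(c("x", "y"), each = N_LANDMARKS), seq_len(N_LANDMARKS))
    missing_cols <- setdiff(c(dialect$id_col, xy), names(df))
    if (length(missing_cols))
      stop("missing columns: ", paste(missing_cols, collapse = ", "))
    m <- as.matrix(df[, xy])
    if (!is.numeric(m)) stop("non-numeric landmark coordinates in ", path)
    bad <- !stats::complete.cases(m) | apply(!is.finite(m), 1L, any)
    if (any(bad)) {
      warning("dropping ", sum(bad), " leaves with missing landmarks: ",
              paste(df[[dialect$id_col]][bad], collapse = ", "))
      df <- df[!bad, , drop = FALSE]
      m <- m[!bad, , drop = FALSE]
    }
    coords <- array(0, c(N_LANDMARKS, 2L, nrow(df)))
    for (i in seq_len(nrow(df)))
      coords[, , i] <- cbind(m[i, 1:N_LANDMARKS], m[i, N_LANDMARKS + 1:N_LANDMARKS])
    records <- .extract_records(df, dialect)
  } else {
    need <- c(dialect$id_col, dialect$landmark_col, dialect$x_col, dialect$y_col)
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols))
      stop("missing columns: ", paste(missing_cols, collapse = ", "))
    ids <- unique(df[[dialect$id_col]])
    counts <- table(df[[dialect$id_col]])
    bad <- names(counts)[counts != N_LANDMARKS]
    if (length(bad))
      stop("leaves without exactly ", N_LANDMARKS, " landmarks: ",
           paste(bad, collapse = ", "))
    coords <- array(0, c(N_LANDMARKS, 2L, length(ids)))
    meta_rows <- integer(length(ids))
    for (i in seq_along(ids)) {
      sub <- df[df[[dialect$id_col]] == ids[i], , drop = FALSE]
      ord <- order(sub[[dialect$landmark_col]])
      sub <- sub[ord, , drop = FALSE]
      if (!identical(as.integer(sub[[dialect$landmark_col]]), seq_len(N_LANDMARKS)))
        stop("leaf ", ids[i], ": landmark indices are not 1..", N_LANDMARKS)
      coords[, , i] <- cbind(sub[[dialect$x_col]], sub[[dialect$y_col]])
      meta_rows[i] <- which(df[[dialect$id_col]] == ids[i])[1]
    }
    if (!all(is.finite(coords))) stop("non-finite landmark coordinates in ", path)
    df <- df[meta_rows, , drop = FALSE]
    records <- .extract_records(df, dialect)
  }
  if (dialect$node_numbering == "tip1" && "node" %in% names(records) &&
      "vine" %in% names(records)) {
    nv <- stats::ave(records$node, records$vine, FUN = max)
    records$node <- convert_node_numbering(records$node, nv)
  }
  landmark_table(coords, records)
}

.extract_records <- function(df, dialect) {
  records <- data.frame(leaf_id = as.character(df[[dialect$id_col]]),
                        stringsAsFactors = FALSE)
  grab <- function(col, name) {
    if (!is.na(col) && col %in% names(df)) records[[name]] <<- df[[col]]
  }
  grab(dialect$species_col, "species")
  grab(dialect$class_col, "class")
  grab(dialect$vine_col, "vine")
  grab(dialect$node_col, "node")
  if ("node" %in% names(records)) records$node <- as.integer(records$node)
  records
}

#' Write a landmark table as a wide CSV
#'
#' Layout mirrors the wide dialect of [read_landmark_table()]: metadata
#' columns followed by `x1..x15, y1..y15`.
#'
#' @param lt A [landmark_table()].
#' @param path Output path.
#' @export
write_landmark_table <- function(lt, path) {
  stopifnot(inherits(lt, "landmark_table"))
  n <- dim(lt$coords)[3]
  xm <- t(lt$coords[, 1, , drop = TRUE])
  ym <- t(lt$coords[, 2, , drop = TRUE])
  if (n == 1L) { xm <- matrix(lt$coords[, 1, 1], 1); ym <- matrix(lt$coords[, 2, 1], 1) }
  colnames(xm) <- paste0("x", seq_len(N_LANDMARKS))
  colnames(ym) <- paste0("y", seq_len(N_LANDMARKS))
  out <- cbind(lt$records, as.data.frame(xm), as.data.frame(ym))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Convert node numbering between tip-first and base-first
#'
#' Raw scan series are often numbered starting at the growing tip
#' (youngest leaf = 1), while heteroblastic analyses number from the shoot
#' base (first emerged leaf = 1). The map `base1 = N - tip1 + 1` converts
#' between the two and is its own inverse.
#'
#' @param node Node index (vectorised).
#' @param nodes_on_vine Total nodes on the vine (recycled).
#' @return Converted node index.
#' @export
convert_node_numbering <- function(node, nodes_on_vine) {
  node <- as.integer(node); nodes_on_vine <- as.integer(nodes_on_vine)
  if (any(node < 1L | node > nodes_on_vine))
    stop("node index out of range 1..nodes_on_vine")
  nodes_on_vine - node + 1L
}

#' Read a normalized elliptic Fourier (NEF) coefficient file
#'
#' The dialect is plain text: per specimen, an id line followed by
#' `n_harmonics` lines of four whitespace-separated reals (coefficient order
#' A, B, C, D). Lines beginning `#` are comments. With
#' `leading_count = TRUE` each id line is followed by an integer line giving
#' the harmonic count (tolerated variant of the format).
#'
#' @param path File path.
#' @param leading_count Whether each record carries a harmonic-count line.
#' @return A `nef` object: list with `ids` (character) and `coeffs` (list of
#'   `n_harmonics x 4` matrices, columns A, B, C, D).
#' @export
read_nef <- function(path, leading_count = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  is_num_line <- function(s) {
    toks <- strsplit(s, "\\s+")[[1]]
    all(!is.na(suppressWarnings(as.numeric(toks))))
  }
  ids <- character(); coeffs <- list(); i <- 1L
  while (i <= length(lines)) {
    id <- lines[i]; i <- i + 1L
    if (leading_count) {
      if (i > length(lines) || !is_num_line(lines[i]))
        stop("expected harmonic count after id '", id, "' at line ", lineno[i - 1L])
      i <- i + 1L
    }
    rows <- list()
    while (i <= length(lines) && is_num_line(lines[i]) &&
           length(strsplit(lines[i], "\\s+")[[1]]) == 4L) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (any(!is.finite(vals)))
        stop("non-numeric coefficient at line ", lineno[i])
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (!length(rows))
      stop("specimen '", id, "' has no coefficient rows")
    m <- do.call(rbind, rows)
    colnames(m) <- c("A", "B", "C", "D")
    ids <- c(ids, id)
    coeffs[[length(coeffs) + 1L]] <- m
  }
  nh <- vapply(coeffs, nrow, 0L)
  if (length(unique(nh)) > 1L)
    stop("ragged harmonic counts across specimens: ",
         paste(unique(nh), collapse = ", "))
  structure(list(ids = ids, coeffs = coeffs, n_harmonics = nh[1]),
            class = "nef")
}

#' @rdname read_nef
#' @param nef A `nef` object.
#' @param digits Significant digits used when formatting coefficients.
#' @export
write_nef <- function(nef, path, digits = 10L) {
  stopifnot(inherits(nef, "nef"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(nef$ids)) {
    writeLines(nef$ids[i], con)
    m <- nef$coeffs[[i]]
    writeLines(apply(m, 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = " ")), con)
  }
  invisible(path)
}

#' @export
print.nef <- function(x, ...) {
  cat("nef:", length(x$ids), "specimens,", x$n_harmonics, "harmonics\n")
  invisible(x)
}

#' Load a binary mask from a PNG image or matrix
#'
#' Reads a greyscale/colour PNG, thresholds it, picks the foreground
#' polarity, and checks connectivity. Pixel coordinates are converted to
#' math convention downstream (x = column, y = height - row) by
#' [trace_boundary()].
#'
#' @param path PNG path, or a numeric/logical matrix already in memory.
#' @param threshold Intensity threshold in `[0, 1]`.
#' @param polarity `"auto"` (foreground = minority class), `"white"` or
#'   `"black"`.
#' @param single_component Require exactly one 8-connected foreground
#'   component.
#' @return Logical matrix, `TRUE` = leaf.
#' @export
load_binary_mask <- function(path, threshold = 0.5,
                             polarity = c("auto", "white", "black"),
                             single_component = TRUE) {
  polarity <- match.arg(polarity)
  if (is.matrix(path)) {
    img <- path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  if (is.logical(img)) {
    white <- img
  } else {
    white <- img > threshold
  }
  mask <- switch(polarity,
    white = white,
    black = !white,
    auto = if (sum(white) <= sum(!white)) white else !white)
  if (!any(mask)) stop("empty foreground after thresholding")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (single_component && ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    stop("mask has ", ncomp, " foreground components (sizes: ",
         paste(sort(sizes, decreasing = TRUE), collapse = ", "),
         "); expected one")
  }
  mask
}

#' Label 8-connected components of a logical mask
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nxt
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}
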