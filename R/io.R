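#' Write a dihedral-scan dataset to CSV
#'
#' Header `conformer_id,scanned_dihedral,scan_angle,e_target,phi_1,...,
#' phi_n`; angles in degrees, energies in kJ/mol, full double precision
#' (round trips reproduce energies beyond 1e-9).
#'
#' @param dataset a [scan_dataset].
#' @param path output file.
#' @return invisibly, `path`.
#' @seealso [read_scan_csv()], [write_typing_csv()]
#' @export
write_scan_csv <- function(dataset, path) {
  if (!inherits(dataset, "scan_dataset")) {
    stop_input("'dataset' must be a scan_dataset")
  }
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dihedral-scan dataset from CSV
#'
#' Parses the layout written by [write_scan_csv()] and validates it:
#' required columns present, numeric fields numeric, conformer ids unique,
#' angles in \eqn{[-180, 180)} (+180 folded to -180), scan angle matching
#' the stored scanned-dihedral value. Errors name the offending column or
#' line.
#'
#' @param path CSV file.
#' @param typing a [dihedral_typing], or a path to a typing CSV (see
#'   [read_typing_csv()]). When `NULL`, every dihedral becomes its own
#'   type.
#' @return a [scan_dataset].
#' @export
read_scan_csv <- function(path, typing = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("conformer_id", "scanned_dihedral", "scan_angle", "e_target")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_input("scan CSV ", path, " is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  phi_cols <- grep("^phi_[0-9]+$", names(df), value = TRUE)
  if (length(phi_cols) == 0L) {
    stop_input("scan CSV ", path, " has no phi_<i> angle columns")
  }
  phi_cols <- phi_cols[order(as.integer(sub("^phi_", "", phi_cols)))]
  for (cn in c("scanned_dihedral", "scan_angle", "e_target", phi_cols)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop_input("non-numeric value in column '", cn, "' at data line ",
                 if (is.na(bad)) "?" else bad, " of ", path)
    }
  }
  if (anyDuplicated(df$conformer_id)) {
    dup <- df$conformer_id[anyDuplicated(df$conformer_id)][1L]
    stop_input("duplicate conformer_id '", dup, "' at data line ",
               which(df$conformer_id == dup)[2L], " of ", path)
  }
  if (is.character(typing)) typing <- read_typing_csv(typing)
  if (is.null(typing)) {
    typing <- dihedral_typing(seq_along(phi_cols))
  }
  scan_dataset(
    angles = as.matrix(df[phi_cols]),
    scanned_dihedral = df$scanned_dihedral,
    scan_angle = df$scan_angle,
    e_target = df$e_target,
    typing = typing,
    conformer_id = df$conformer_id
  )
}

#' Write / read a dihedral typing table
#'
#' CSV with columns `dihedral_index,type_index,type_label` (1-based
#' indices).
#'
#' @param typing a [dihedral_typing].
#' @param path file path.
#' @return `write_typing_csv()` returns `path` invisibly;
#'   `read_typing_csv()` returns a [dihedral_typing].
#' @export
write_typing_csv <- function(typing, path) {
  if (!inherits(typing, "dihedral_typing")) {
    stop_input("'typing' must be a dihedral_typing")
  }
  labels <- if (is.null(typing$type_labels)) "" else
    typing$type_labels[typing$type_of]
  df <- data.frame(dihedral_index = seq_len(typing$n_dihedrals),
                   type_index = typing$type_of,
                   type_label = labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_typing_csv
#' @export
read_typing_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("dihedral_index", "type_index")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_input("typing CSV ", path, " is missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  ord <- order(df$dihedral_index)
  df <- df[ord, ]
  if (!identical(df$dihedral_index, seq_len(nrow(df)))) {
    stop_input("typing CSV ", path,
               " must enumerate dihedral_index 1..n without gaps")
  }
  labels <- NULL
  if ("type_label" %in% names(df) && any(nzchar(df$type_label))) {
    labels <- vapply(seq_len(max(df$type_index)), function(g) {
      lab <- unique(df$type_label[df$type_index == g])
      lab <- lab[nzchar(lab)]
      if (length(lab) == 0L) "" else lab[1L]
    }, character(1L))
    if (!any(nzchar(labels))) labels <- NULL
  }
  dihedral_typing(df$type_index, labels)
}

#' Write / read Fourier coefficients as CSV
#'
#' Columns `type_index,k1..k4` (or `k1..k3`) plus an optional final
#' `offset` row stored as `type_index = 0`.
#'
#' @param params a [fourier_params].
#' @param path file path.
#' @return `write_params_csv()` returns `path` invisibly;
#'   `read_params_csv()` returns a [fourier_params].
#' @export
write_params_csv <- function(params, path) {
  if (!inherits(params, "fourier_params")) {
    stop_input("'params' must be a fourier_params")
  }
  k <- params$k
  df <- data.frame(type_index = seq_len(nrow(k)))
  for (j in seq_len(ncol(k))) df[[paste0("k", j)]] <- sprintf("%.17g", k[, j])
  if (params$offset != 0) {
    off <- c(0, sprintf("%.17g", params$offset),
             rep("0", ncol(k) - 1L))
    df <- rbind(df, off)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kcols <- grep("^k[0-9]$", names(df), value = TRUE)
  if (!("type_index" %in% names(df)) || length(kcols) < 3L) {
    stop_input("parameter CSV ", path,
               " must have columns type_index and k1..k3 or k1..k4")
  }
  kcols <- kcols[order(kcols)]
  offset <- 0
  off_row <- df$type_index == 0
  if (any(off_row)) {
    offset <- as.numeric(df[[kcols[1L]]][off_row][1L])
    df <- df[!off_row, , drop = FALSE]
  }
  df <- df[order(df$type_index), , drop = FALSE]
  fourier_params(as.matrix(df[kcols]), offset = offset)
}

#' Write / read Ryckaert-Bellemans coefficients as CSV
#'
#' Columns `type_index,C0..C5`, plus an optional `type_index = 0` row
#' carrying the energy offset in `C0`.
#'
#' @param params an [rb_params].
#' @param path file path.
#' @return `write_rb_csv()` returns `path` invisibly; `read_rb_csv()`
#'   returns an [rb_params].
#' @export
write_rb_csv <- function(params, path) {
  if (!inherits(params, "rb_params")) {
    stop_input("'params' must be an rb_params")
  }
  df <- data.frame(type_index = seq_len(params$n_types))
  for (n in 0:5) df[[paste0("C", n)]] <- sprintf("%.17g", params$C[, n + 1L])
  if (params$offset != 0) {
    df <- rbind(df, c(0, sprintf("%.17g", params$offset), rep("0", 5L)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rb_csv
#' @export
read_rb_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ccols <- paste0("C", 0:5)
  if (!("type_index" %in% names(df)) || !all(ccols %in% names(df))) {
    stop_input("RB CSV ", path, " must have columns type_index and C0..C5")
  }
  offset <- 0
  off_row <- df$type_index == 0
  if (any(off_row)) {
    offset <- as.numeric(df$C0[off_row][1L])
    df <- df[!off_row, , drop = FALSE]
  }
  df <- df[order(df$type_index), , drop = FALSE]
  rb_params(as.matrix(df[ccols]), offset = offset)
}

#' Export fitted torsional parameters as a GROMACS topology fragment
#'
#' Writes a `[ dihedraltypes ]` block. `style = "rb_func3"` converts to
#' Ryckaert-Bellemans coefficients and writes function type 3 lines
#' (`ai aj ak al 3 C0..C5`); `style = "fourier_func5"` writes function
#' type 5 lines with the four Fourier coefficients. Atom names come from
#' the typing's atom-type quadruple labels (`"CT-OS-P-OS"` etc.), which
#' must be present. Output is fixed-width with 6 decimals and contains no
#' timestamps, so identical inputs give byte-identical files. The fitted
#' energy offset, having no force-field field, is written as a comment.
#'
#' @param params a [fourier_params] or [rb_params] (the latter only with
#'   `style = "rb_func3"`).
#' @param typing a [dihedral_typing] with `type_labels`.
#' @param path output file.
#' @param style `"rb_func3"` or `"fourier_func5"`.
#' @return invisibly, `path`.
#' @examples
#' p <- fourier_params(matrix(c(1, 0, 0, 0), 1, 4))
#' ty <- dihedral_typing(1, "CT-OS-P-OS")
#' f <- tempfile(fileext = ".itp")
#' write_itp(p, ty, f)   # RB line: 1.000000 -1.000000 0 0 0 0
#' @export
write_itp <- function(params, typing, path,
                      style = c("rb_func3", "fourier_func5")) {
  style <- match.arg(style)
  if (!inherits(typing, "dihedral_typing")) {
    stop_input("'typing' must be a dihedral_typing")
  }
  if (is.null(typing$type_labels)) {
    stop_input("typing has no type_labels (atom-type quadruples); ",
               "they are required for .itp export")
  }
  if (inherits(params, "fourier_params")) {
    fp <- params
    rb <- fourier_to_rb(params)
  } else if (inherits(params, "rb_params")) {
    if (style == "fourier_func5") {
      stop_input("fourier_func5 export needs fourier_params ",
                 "(use rb_to_fourier() first)")
    }
    fp <- NULL
    rb <- params
  } else {
    stop_input("'params' must be fourier_params or rb_params")
  }
  if (rb$n_types != typing$n_types) {
    stop_input("parameter set has ", rb$n_types, " types but typing has ",
               typing$n_types)
  }
  atoms <- strsplit(typing$type_labels, "-", fixed = TRUE)
  bad <- which(lengths(atoms) != 4L)
  if (length(bad) > 0L) {
    stop_input("type label '", typing$type_labels[bad[1L]],
               "' is not an atom-type quadruple (expected A-B-C-D)")
  }
  lines <- c(
    "; torsional parameters exported by torsionfit",
    sprintf("; energy offset (not a force-field parameter): %.6f kJ/mol",
            rb$offset),
    "[ dihedraltypes ]"
  )
  rbC <- rb$C + 0          # normalize IEEE negative zeros for printing
  if (style == "rb_func3") {
    lines <- c(lines,
               ";  ai    aj    ak    al  func        C0        C1        C2        C3        C4        C5")
    for (g in seq_len(typing$n_types)) {
      lines <- c(lines, sprintf(
        "%5s %5s %5s %5s %5d %11.6f %11.6f %11.6f %11.6f %11.6f %11.6f",
        atoms[[g]][1L], atoms[[g]][2L], atoms[[g]][3L], atoms[[g]][4L], 3L,
        rbC[g, 1L], rbC[g, 2L], rbC[g, 3L], rbC[g, 4L], rbC[g, 5L],
        rbC[g, 6L]))
    }
  } else {
    k <- fp$k + 0            # drop negative-zero signs
    if (ncol(k) == 3L) k <- cbind(k, 0)
    lines <- c(lines,
               ";  ai    aj    ak    al  func        C1        C2        C3        C4")
    for (g in seq_len(typing$n_types)) {
      lines <- c(lines, sprintf(
        "%5s %5s %5s %5s %5d %11.6f %11.6f %11.6f %11.6f",
        atoms[[g]][1L], atoms[[g]][2L], atoms[[g]][3L], atoms[[g]][4L], 5L,
        k[g, 1L], k[g, 2L], k[g, 3L], k[g, 4L]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse Fourier coefficients back from a function-type-5 .itp fragment
#'
#' Reads `[ dihedraltypes ]` lines with function type 5 as written by
#' [write_itp()] and reconstructs the coefficient set and typing labels.
#'
#' @param path .itp file.
#' @return a list with `params` (a [fourier_params]) and `labels`
#'   (character vector of atom-type quadruples).
#' @export
read_itp_fourier <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path)
  data_lines <- grep("^\\s*[^;\\[]", lines, value = TRUE)
  rows <- lapply(data_lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  rows <- Filter(function(r) length(r) == 9L && r[5L] == "5", rows)
  if (length(rows) == 0L) {
    stop_input("no function-type-5 dihedraltypes lines in ", path)
  }
  k <- t(vapply(rows, function(r) as.numeric(r[6:9]), numeric(4L)))
  labels <- vapply(rows, function(r) paste(r[1:4], collapse = "-"),
                   character(1L))
  offset <- 0
  off_line <- grep("^; energy offset", lines, value = TRUE)
  if (length(off_line) > 0L) {
    offset <- as.numeric(sub(".*: (-?[0-9.eE+-]+) kJ/mol$", "\\1",
                             off_line[1L]))
  }
  list(params = fourier_params(k, offset = offset), labels = labels)
}
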