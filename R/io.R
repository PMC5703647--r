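# Configuration files, image stacks, tables and run provenance.
#
# Conventions: image coordinates are 0-based in files, row-major, origin
# top-left (in R, matrices are 1-based; converters are explicit);
# simulation coordinates are continuous with origin bottom-left.  Stacks
# are stored as plain-text ASCII PGM (P2, 8-bit) so that everything the
# package writes is text.

.run_keys <- c("init", "n_cells", "duration", "frame_interval", "burn_in",
               "seed", "record_tissues", "relax_tol", "output_dir")

#' Load and validate a flat key=value configuration file
#'
#' Recognised keys: every \code{model_params} field plus
#' \code{init, n_cells, duration, frame_interval, burn_in, seed,
#' record_tissues, relax_tol, output_dir}.  Unknown keys and invariant
#' violations are reported as an itemized error.  An empty file yields
#' the full wild-type default set.
#'
#' @param path file path.
#' @return List with \code{params} (a \code{vm_params}) and \code{run}
#'   (driver settings), both fully populated.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  errs <- character(0)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      errs <- c(errs, sprintf("malformed line (expected key = value): '%s'", ln))
      next
    }
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num)) num
    else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
    else val
  }
  pfields <- setdiff(names(model_params()), "alpha")
  unknown <- setdiff(names(kv), c(pfields, "alpha", .run_keys))
  if (length(unknown)) errs <- c(errs, paste("unknown key:", unknown))
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  params <- tryCatch(do.call(model_params, kv[names(kv) %in% c(pfields, "alpha")]),
                     error = function(e) stop("invalid config:\n  ",
                                              conditionMessage(e)))
  run <- list(init = "honeycomb", n_cells = 64, duration = 30,
              frame_interval = 0.5, burn_in = 20, seed = params$seed,
              record_tissues = FALSE, relax_tol = 1e-3, output_dir = ".")
  run[names(kv)[names(kv) %in% .run_keys]] <- kv[names(kv) %in% .run_keys]
  list(params = params, run = run)
}

#' @rdname load_config
#' @param config list as returned by \code{load_config}.
#' @export
save_config <- function(config, path) {
  p <- config$params
  lines <- c(
    vapply(setdiff(names(unclass(p)), "alpha"), function(k)
      sprintf("%s = %s", k, format(p[[k]], digits = 17)), ""),
    vapply(names(config$run), function(k)
      sprintf("%s = %s", k, format(config$run[[k]], digits = 17)), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an 8-bit image stack as ASCII PGM files
#'
#' One file per frame (\code{<prefix>_NNNN.pgm}, P2 format) plus a
#' metadata sidecar \code{<prefix>_meta.txt} (px_size_um,
#' frame_interval_s).
#'
#' @param stack list of integer matrices with values in 0..255.
#' @param prefix path prefix.
#' @param px_size_um,frame_interval_s metadata.
#' @return \code{prefix} invisibly (write); list with \code{stack},
#'   \code{px_size_um}, \code{frame_interval_s} (read).
#' @export
write_stack <- function(stack, prefix, px_size_um = 1, frame_interval_s = 30) {
  for (i in seq_along(stack)) {
    m <- stack[[i]]
    if (any(m < 0 | m > 255)) stop("stack is not 8-bit (values outside 0..255)")
    m <- round(m)
    f <- sprintf("%s_%04d.pgm", prefix, i)
    con <- file(f, "w")
    writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
    write(t(m), con, ncolumns = ncol(m))
    close(con)
  }
  writeLines(c(paste("px_size_um =", px_size_um),
               paste("frame_interval_s =", frame_interval_s),
               paste("n_frames =", length(stack))),
             paste0(prefix, "_meta.txt"))
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  meta_f <- paste0(prefix, "_meta.txt")
  px <- 1; fi <- 30
  if (file.exists(meta_f)) {
    meta <- load_kv(meta_f)
    px <- meta$px_size_um %||% 1
    fi <- meta$frame_interval_s %||% 30
  } else {
    warning("missing metadata sidecar; applying defaults (1 um/px, 30 s)")
  }
  files <- sort(Sys.glob(sprintf("%s_*.pgm", prefix)))
  if (!length(files)) stop("no frames found for prefix ", prefix)
  stack <- lapply(files, function(f) {
    txt <- scan(f, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") stop("not an ASCII PGM (P2): ", f)
    nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
    maxv <- as.integer(txt[4])
    if (maxv > 255) stop("stack is not 8-bit: ", f)
    vals <- as.integer(txt[-(1:4)])
    matrix(vals, nr, nc, byrow = TRUE)
  })
  list(stack = stack, px_size_um = px, frame_interval_s = fi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_kv <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write / read a delimited table with a documented header
#'
#' Tab-separated, header row required; reading verifies an expected
#' header when supplied.
#'
#' @param x data.frame.
#' @param path file path.
#' @param expected_cols optional character vector for schema checking.
#' @return \code{path} invisibly (write) / data.frame (read).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path, expected_cols = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.null(expected_cols) && !identical(names(x), expected_cols)) {
    stop(sprintf("schema mismatch in %s: found [%s], expected [%s]",
                 path, paste(names(x), collapse = ", "),
                 paste(expected_cols, collapse = ", ")))
  }
  x
}

#' Write a run manifest
#'
#' JSON document recording the resolved configuration, seed, package
#' version, wall-clock start/end, and md5 digests of the listed files.
#'
#' @param dir run directory (one manifest per run directory).
#' @param config resolved config list.
#' @param seed integer seed.
#' @param files character vector of produced files.
#' @param started,finished POSIXct timestamps.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, files = character(0),
                           started = Sys.time(), finished = Sys.time()) {
  if (!is.null(config$params)) config$params <- unclass(config$params)
  manifest <- list(
    package = "vertexflux",
    version = as.character(utils::packageVersion("vertexflux")),
    seed = seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = if (length(files)) {
      data.frame(path = files, md5 = unname(tools::md5sum(files)),
                 bytes = unname(file.size(files)))
    } else NULL)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
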