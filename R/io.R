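# File interchange: PLY vertex clouds, session tables, and on-disk model
# serialization (flat binary arrays + JSON metadata).

#' Write a vertex cloud to PLY
#'
#' @param vertices flat V*3 numeric vector (interleaved xyz) or V x 3 matrix.
#' @param path output file.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @export
write_ply <- function(vertices, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  Vm <- if (is.matrix(vertices)) vertices else
    matrix(vertices, ncol = 3L, byrow = TRUE)
  header <- c("ply",
              paste("format", format, "1.0"),
              paste("element vertex", nrow(Vm)),
              "property float x", "property float y", "property float z",
              "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(format(Vm, digits = 9, scientific = FALSE,
                              trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(Vm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a PLY vertex cloud
#'
#' Supports ASCII and binary little-endian files with float xyz properties.
#'
#' @param path PLY file.
#' @return V x 3 numeric matrix.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 100L) stop("malformed PLY header")
  }
  fmt <- sub("^format ([a-z_]+).*", "\\1", grep("^format", header, value = TRUE))
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  if (fmt == "ascii") {
    vals <- scan(con, what = numeric(), n = nv * 3L, quiet = TRUE)
  } else if (fmt == "binary_little_endian") {
    vals <- readBin(con, numeric(), n = nv * 3L, size = 4L, endian = "little")
  } else stop("unsupported PLY format: ", fmt)
  matrix(vals, ncol = 3L, byrow = TRUE)
}

#' Write / read a session as TSV
#'
#' Columns: trial, the candidate stimulus indices of the array, chosen
#' position, chosen stimulus index, rating.
#'
#' @param session a `session` (see [simulate_session()]).
#' @param path file path.
#' @export
write_session_tsv <- function(session, path) {
  arrays <- attr(session, "arrays")
  colnames(arrays) <- paste0("cand", seq_len(ncol(arrays)))
  df <- cbind(data.frame(trial = session$trial), as.data.frame(arrays),
              data.frame(chosen_index = session$chosen_index,
                         chosen_stimulus = attr(session, "chosen_stimulus"),
                         rating = session$rating))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_tsv
#' @export
read_session_tsv <- function(path) {
  utils::read.delim(path, sep = "\t")
}

#' Serialize / load a fitted generative face model
#'
#' The model is written as a directory of flat little-endian double arrays
#' plus a JSON metadata file recording shapes, design coding and the
#' component scaling convention.
#'
#' @param model a `gmf_model`.
#' @param dir output directory (created).
#' @export
save_gmf_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- c("A_shape", "U_shape", "s_shape", "V_shape", "scale_shape")
  if (!is.null(model$K_texture))
    arrays <- c(arrays, "A_texture", "U_texture", "s_texture", "V_texture",
                "scale_texture")
  meta <- list(format_version = 1L,
               n_exemplars = model$n_exemplars,
               n_vertices = model$n_vertices,
               K_shape = model$K_shape,
               K_texture = model$K_texture,
               component_scaling = "unit-variance (d / sqrt(n - 1))",
               # named list keeps names through JSON (vectors would not)
               design_spec = utils::modifyList(
                 model$design_spec,
                 list(have = as.list(model$design_spec$have))),
               shapes = lapply(model[arrays], function(a)
                 if (is.matrix(a)) dim(a) else length(a)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in arrays) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
    writeBin(as.numeric(model[[nm]]), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname save_gmf_model
#' @export
load_gmf_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  model <- list(n_exemplars = meta$n_exemplars,
                n_vertices = meta$n_vertices,
                K_shape = meta$K_shape,
                K_texture = meta$K_texture)
  spec <- meta$design_spec
  spec$have <- unlist(spec$have)
  model$design_spec <- spec
  for (nm in names(meta$shapes)) {
    shp <- unlist(meta$shapes[[nm]])
    con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
    vals <- readBin(con, numeric(), n = prod(shp), size = 8L,
                    endian = "little")
    close(con)
    model[[nm]] <- if (length(shp) == 2L) matrix(vals, shp[1L], shp[2L]) else vals
  }
  structure(model, class = "gmf_model")
}
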