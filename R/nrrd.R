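## Minimal NRRD reader/writer (ASCII encoding only).
## Covers exactly what the phantom store needs: 3-D double or uint8 arrays
## with per-axis spacing ("space directions", diagonal) and "space origin".
## ASCII encoding keeps phantom stores plain text.

#' Write / read a 3-D array as NRRD (ASCII encoding)
#'
#' @param x 3-D numeric or logical array.
#' @param path output file.
#' @param spacing voxel size per axis, mm.
#' @param origin grid corner, mm.
#' @return `read_nrrd` returns a list with `data` (3-D array), `spacing`,
#'   `origin` and `type`.
#' @keywords internal
#' @export
write_nrrd <- function(x, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(x)) != 3L) stopf("NRRD writer expects a 3-D array")
  is_mask <- is.logical(x)
  type <- if (is_mask) "uint8" else "double"
  dirs <- sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                  spacing[1], spacing[2], spacing[3])
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(x), collapse = " ")),
           paste0("space dimension: 3"),
           paste0("space directions: ", dirs),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   origin[1], origin[2], origin[3]),
           "encoding: ascii",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vals <- if (is_mask) as.integer(x) else as.vector(x)
  txt <- if (is_mask) as.character(vals) else sprintf("%.17g", vals)
  ## NRRD ascii data is whitespace-separated, fastest axis first (matches
  ## R column-major order)
  writeLines(paste(txt, collapse = " "), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1L], "NRRD")) stopf("%s is not an NRRD file", path)
  blank <- which(lines == "")[1L]
  if (is.na(blank)) stopf("%s: malformed NRRD (no header terminator)", path)
  hdr <- lines[2:(blank - 1L)]
  fields <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexpr(": ", h), invert = TRUE)[[1L]]
    if (length(kv) == 2L) fields[[tolower(kv[1L])]] <- kv[2L]
  }
  if (!identical(fields[["encoding"]], "ascii"))
    stopf("%s: only ascii encoding is supported", path)
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1L]])
  if (length(sizes) != 3L) stopf("%s: expected 3-D data", path)
  nums <- function(s) as.numeric(regmatches(s, gregexpr("[-0-9.eE+]+", s))[[1L]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    v <- nums(fields[["space directions"]])
    spacing <- c(v[1L], v[5L], v[9L])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- nums(fields[["space origin"]])
  data <- scan(text = lines[(blank + 1L):length(lines)],
               what = numeric(), quiet = TRUE)
  if (length(data) != prod(sizes))
    stopf("%s: expected %d values, found %d", path, prod(sizes), length(data))
  type <- fields[["type"]]
  arr <- array(if (identical(type, "uint8")) data != 0 else data, dim = sizes)
  list(data = arr, spacing = spacing, origin = origin, type = type)
}

#' Save / load a phantom structure set as NRRD files
#'
#' Writes `density.nrrd`, one `mask_<name>.nrrd` per structure, and a
#' `phantom.json` manifest (structure names, roles, spec echo) to `dir`.
#'
#' @param ss a `vhee_structure_set`.
#' @param dir directory (created if needed).
#' @return `load_phantom` returns a `vhee_structure_set`.
#' @export
save_phantom <- function(ss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- ss$grid
  write_nrrd(g$density, file.path(dir, "density.nrrd"), g$spacing, g$origin)
  for (s in ss$structures)
    write_nrrd(s$mask, file.path(dir, paste0("mask_", s$name, ".nrrd")),
               g$spacing, g$origin)
  spec <- attr(ss, "spec")
  manifest <- list(
    structures = lapply(unname(ss$structures),
                        function(s) list(name = s$name, role = s$role)),
    spec = if (!is.null(spec)) unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_phantom
#' @export
load_phantom <- function(dir) {
  mf_path <- file.path(dir, "phantom.json")
  if (!file.exists(mf_path)) stopf("no phantom.json manifest in %s", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  dens <- read_nrrd(file.path(dir, "density.nrrd"))
  grid <- image_grid(dens$data, spacing = dens$spacing, origin = dens$origin)
  structures <- lapply(manifest$structures, function(e) {
    f <- file.path(dir, paste0("mask_", e$name, ".nrrd"))
    if (!file.exists(f)) stopf("missing structure file %s", f)
    msk <- read_nrrd(f)
    if (!identical(dim(msk$data), grid$shape))
      stopf("mask '%s' shape (%s) does not match the density grid (%s)",
            e$name, paste(dim(msk$data), collapse = "x"),
            paste(grid$shape, collapse = "x"))
    structure_mask(e$name, msk$data, e$role)
  })
  ss <- structure_set(grid, structures)
  if (!is.null(manifest$spec)) {
    sp <- manifest$spec
    attr(ss, "spec") <- structure(
      list(recipe = sp$recipe, spacing = sp$spacing,
           seed = as.integer(sp$seed),
           params = lapply(sp$params, function(v) unlist(v))),
      class = "vhee_phantom_spec")
  }
  ss
}
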