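#' @useDynLib raterseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- format dispatch ---------------------------------------------------

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.mha$|\\.mhd$", lp)) return("meta")
  stop(sprintf("unsupported volume format: '%s' (expected .nii/.nii.gz, .nrrd, .mha/.mhd)",
               basename(path)), call. = FALSE)
}

read_raw_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path), call. = FALSE)
  switch(volume_format(path),
         nifti = read_nifti_raw(path),
         nrrd  = read_nrrd_raw(path),
         meta  = read_meta_raw(path))
}

#' Read a binary label volume
#'
#' Reads a segmentation mask from NIfTI-1 (`.nii`, `.nii.gz`), NRRD
#' (`.nrrd`) or MetaImage (`.mha`, `.mhd`) and binarizes it: any nonzero
#' voxel becomes 1. A warning is emitted when more than one distinct
#' nonzero label is present (exporter dialects differ). Voxel spacing is
#' taken from the header and must be present and positive; the third array
#' axis is taken as the cranio-caudal axis with slice index increasing from
#' apex to base.
#'
#' @param path file path
#' @return a [label_volume()]
#' @export
read_label_volume <- function(path) {
  rv <- read_raw_volume(path)
  v <- rv$voxels
  if (any(!is.finite(v)))
    stop(sprintf("'%s': non-finite voxel values", basename(path)), call. = FALSE)
  if (max(abs(v - round(v))) > 1e-6)
    stop(sprintf("'%s': voxel values are not integer-coded; refusing to binarize",
                 basename(path)), call. = FALSE)
  nz <- unique(v[v != 0])
  if (length(nz) > 1)
    warning(sprintf("'%s': %d distinct nonzero labels collapsed to 1",
                    basename(path), length(nz)), call. = FALSE)
  label_volume(v, rv$spacing)
}

#' Read a scalar intensity volume
#'
#' @param path file path (NIfTI, NRRD or MetaImage)
#' @return an [intensity_volume()]
#' @export
read_intensity_volume <- function(path) {
  rv <- read_raw_volume(path)
  intensity_volume(rv$voxels, rv$spacing)
}

#' Write a label or intensity volume
#'
#' Format is chosen from the file extension (`.nii`/`.nii.gz`, `.nrrd`,
#' `.mha`). Label volumes are written as unsigned 8-bit integers,
#' intensity volumes as 64-bit floats (32-bit for NIfTI).
#'
#' @param vol a [label_volume()] or [intensity_volume()]
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  is_label <- is_label_volume(vol)
  if (!is_label && !inherits(vol, "intensity_volume"))
    stop("vol must be a label_volume or intensity_volume", call. = FALSE)
  switch(volume_format(path),
         nifti = write_nifti_vol(vol, path, is_label),
         nrrd  = write_nrrd_vol(vol, path, is_label),
         meta  = write_meta_vol(vol, path, is_label))
  invisible(path)
}

# ---- NIfTI (via RNifti) ------------------------------------------------

read_nifti_raw <- function(path) {
  im <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(im)
  arr <- as.array(im)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
    sp <- sp[1:3]
  }
  if (length(dim(arr)) != 3L)
    stop(sprintf("'%s': expected a 3D volume, got %dD", basename(path),
                 length(dim(arr))), call. = FALSE)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("'%s': missing or nonpositive voxel spacing in header",
                 basename(path)), call. = FALSE)
  list(voxels = arr, spacing = as.numeric(sp[1:3]))
}

write_nifti_vol <- function(vol, path, is_label) {
  arr <- vol$voxels
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path,
                     datatype = if (is_label) "uint8" else "float")
}

# ---- NRRD (minimal reader/writer) --------------------------------------
# Detached NRRD headers and exotic encodings are out of scope; raw and
# gzip encodings of common little-endian scalar types are supported.

split_header_data <- function(path, sep) {
  n <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n)
  hit <- NULL
  sep_raw <- charToRaw(sep)
  ls <- length(sep_raw)
  idx <- which(bytes == sep_raw[1])
  for (i in idx) {
    if (i + ls - 1 <= length(bytes) &&
        identical(bytes[i:(i + ls - 1)], sep_raw)) { hit <- i; break }
  }
  if (is.null(hit))
    stop(sprintf("'%s': malformed header (no header/data separator)",
                 basename(path)), call. = FALSE)
  list(header = rawToChar(bytes[1:(hit - 1)]),
       data = bytes[(hit + ls):length(bytes)])
}

nrrd_type_map <- c("uint8" = "integer", "uchar" = "integer",
                   "unsigned char" = "integer",
                   "int8" = "integer", "signed char" = "integer",
                   "int16" = "integer", "short" = "integer",
                   "uint16" = "integer", "unsigned short" = "integer",
                   "int32" = "integer", "int" = "integer",
                   "uint32" = "integer", "unsigned int" = "integer",
                   "float" = "double", "double" = "double")
nrrd_type_size <- c("uint8" = 1, "uchar" = 1, "unsigned char" = 1,
                    "int8" = 1, "signed char" = 1,
                    "int16" = 2, "short" = 2, "uint16" = 2,
                    "unsigned short" = 2, "int32" = 4, "int" = 4,
                    "uint32" = 4, "unsigned int" = 4,
                    "float" = 4, "double" = 8)

decode_scalars <- function(data, type, n) {
  what <- nrrd_type_map[[type]]
  size <- nrrd_type_size[[type]]
  signed <- !(type %in% c("uint8", "uchar", "unsigned char",
                          "uint16", "unsigned short"))
  vals <- readBin(data, what, n = n, size = size,
                  signed = if (size < 4) signed else TRUE,
                  endian = "little")
  if (length(vals) < n)
    stop("volume data truncated", call. = FALSE)
  vals
}

read_nrrd_raw <- function(path) {
  hd <- split_header_data(path, "\n\n")
  lines <- strsplit(gsub("\r", "", hd$header), "\n")[[1]]
  if (!grepl("^NRRD", lines[1]))
    stop(sprintf("'%s': not an NRRD file", basename(path)), call. = FALSE)
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):[ =]*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (!identical(fields[["dimension"]], "3"))
    stop(sprintf("'%s': only 3-dimensional NRRD supported", basename(path)),
         call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  if (is.null(type) || !type %in% names(nrrd_type_map))
    stop(sprintf("'%s': unsupported NRRD type '%s'", basename(path),
                 type %||% "?"), call. = FALSE)
  endian <- fields[["endian"]]
  if (!is.null(endian) && endian != "little")
    stop(sprintf("'%s': only little-endian NRRD supported", basename(path)),
         call. = FALSE)
  spacing <- nrrd_spacing(fields, basename(path))
  enc <- fields[["encoding"]] %||% "raw"
  data <- hd$data
  if (enc %in% c("gzip", "gz")) {
    data <- memDecompress(data, type = "gzip")
  } else if (enc != "raw") {
    stop(sprintf("'%s': unsupported NRRD encoding '%s'", basename(path), enc),
         call. = FALSE)
  }
  vals <- decode_scalars(data, type, prod(sizes))
  list(voxels = array(vals, dim = sizes), spacing = spacing)
}

nrrd_spacing <- function(fields, name) {
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(vecs, function(v) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1))
  } else {
    stop(sprintf("'%s': no voxel spacing in NRRD header (spacings/space directions)",
                 name), call. = FALSE)
  }
  if (length(sp) != 3 || any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("'%s': invalid voxel spacing in NRRD header", name),
         call. = FALSE)
  sp
}

write_nrrd_vol <- function(vol, path, is_label) {
  arr <- vol$voxels
  type <- if (is_label) "uint8" else "double"
  header <- paste0(
    "NRRD0004\n",
    "type: ", type, "\n",
    "dimension: 3\n",
    "sizes: ", paste(dim(arr), collapse = " "), "\n",
    "endian: little\n",
    "encoding: gzip\n",
    "spacings: ", paste(format(vol$spacing, digits = 17), collapse = " "), "\n",
    "\n")
  payload <- if (is_label) {
    writeBin(as.integer(arr), raw(), size = 1)
  } else {
    writeBin(as.double(arr), raw(), size = 8, endian = "little")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(memCompress(payload, type = "gzip"), con)
}

# ---- MetaImage (minimal reader/writer) ---------------------------------

meta_type_map <- c("MET_UCHAR" = "uint8", "MET_CHAR" = "int8",
                   "MET_SHORT" = "int16", "MET_USHORT" = "uint16",
                   "MET_INT" = "int32", "MET_UINT" = "uint32",
                   "MET_FLOAT" = "float", "MET_DOUBLE" = "double")

read_meta_raw <- function(path) {
  hd <- split_header_data(path, "ElementDataFile")
  lines <- strsplit(gsub("\r", "", hd$header), "\n")[[1]]
  fields <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[kv[2]]] <- trimws(kv[3])
  }
  # remainder of hd$data is "= <file>\n" then payload (if LOCAL)
  rest <- hd$data
  nl <- which(rest == charToRaw("\n"))[1]
  if (is.na(nl))
    stop(sprintf("'%s': malformed MetaImage header", basename(path)), call. = FALSE)
  datafile <- trimws(sub("^\\s*=\\s*", "", rawToChar(rest[1:(nl - 1)])))
  if (!identical(fields[["NDims"]], "3"))
    stop(sprintf("'%s': only 3D MetaImage supported", basename(path)), call. = FALSE)
  if (identical(tolower(fields[["CompressedData"]] %||% "false"), "true"))
    stop(sprintf("'%s': compressed MetaImage not supported", basename(path)),
         call. = FALSE)
  if (identical(tolower(fields[["BinaryDataByteOrderMSB"]] %||% "false"), "true"))
    stop(sprintf("'%s': big-endian MetaImage not supported", basename(path)),
         call. = FALSE)
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spc <- fields[["ElementSpacing"]]
  if (is.null(spc))
    stop(sprintf("'%s': no ElementSpacing in MetaImage header", basename(path)),
         call. = FALSE)
  spacing <- as.numeric(strsplit(spc, "\\s+")[[1]])
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s': invalid ElementSpacing", basename(path)), call. = FALSE)
  mtype <- fields[["ElementType"]]
  if (is.null(mtype) || !mtype %in% names(meta_type_map))
    stop(sprintf("'%s': unsupported ElementType '%s'", basename(path),
                 mtype %||% "?"), call. = FALSE)
  data <- if (identical(datafile, "LOCAL")) {
    rest[(nl + 1):length(rest)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("'%s': ElementDataFile '%s' not found", basename(path),
                   datafile), call. = FALSE)
    readBin(rawpath, "raw", file.info(rawpath)$size)
  }
  vals <- decode_scalars(data, meta_type_map[[mtype]], prod(sizes))
  list(voxels = array(vals, dim = sizes), spacing = spacing)
}

write_meta_vol <- function(vol, path, is_label) {
  arr <- vol$voxels
  header <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    "DimSize = ", paste(dim(arr), collapse = " "), "\n",
    "ElementSpacing = ", paste(format(vol$spacing, digits = 17), collapse = " "), "\n",
    "ElementType = ", if (is_label) "MET_UCHAR" else "MET_DOUBLE", "\n",
    "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  if (is_label) {
    writeBin(as.integer(arr), con, size = 1)
  } else {
    writeBin(as.double(arr), con, size = 8, endian = "little")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cohort manifest ---------------------------------------------------

manifest_columns <- c("case_id", "rater_id", "experience_group",
                      "structure", "sequence_type", "path")
experience_groups <- c("expert", "senior", "junior")

#' Load and validate a multi-rater cohort
#'
#' Reads a cohort manifest (CSV or JSON with columns
#' `case_id,rater_id,experience_group,structure,sequence_type,path`),
#' validates the schema — every (case, rater) must have both a WG and a TZ
#' mask, each rater's experience group must be constant, all paths must
#' resolve — and, when `load_volumes = TRUE`, reads every mask and checks
#' that shapes and spacings agree within each case.
#'
#' @param manifest_path path to the manifest file; relative mask paths are
#'   resolved against its directory
#' @param load_volumes read all masks into memory (default TRUE)
#' @return an object of class `rater_cohort`: the manifest data.frame plus,
#'   when loaded, a nested `volumes[[case_id]][[structure]][[rater_id]]`
#'   list of [label_volume()]s and a `rater_groups` named vector
#' @export
load_cohort <- function(manifest_path, load_volumes = TRUE) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' does not exist", manifest_path), call. = FALSE)
  man <- if (grepl("\\.json$", tolower(manifest_path))) {
    as.data.frame(jsonlite::fromJSON(manifest_path))
  } else {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(manifest_columns, names(man))
  if (length(missing_cols))
    stop(sprintf("manifest lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  man <- man[, manifest_columns]
  bad_grp <- setdiff(unique(man$experience_group), experience_groups)
  if (length(bad_grp))
    stop(sprintf("unknown experience group(s): %s",
                 paste(bad_grp, collapse = ", ")), call. = FALSE)
  bad_st <- setdiff(unique(man$structure), c("WG", "TZ"))
  if (length(bad_st))
    stop(sprintf("unknown structure(s): %s (expected WG, TZ)",
                 paste(bad_st, collapse = ", ")), call. = FALSE)
  grp_per_rater <- tapply(man$experience_group, man$rater_id,
                          function(g) length(unique(g)))
  if (any(grp_per_rater > 1))
    stop(sprintf("experience group not constant for rater(s): %s",
                 paste(names(grp_per_rater)[grp_per_rater > 1], collapse = ", ")),
         call. = FALSE)
  # completeness: both structures per (case, rater, sequence)
  key <- interaction(man$case_id, man$rater_id, man$sequence_type, drop = TRUE)
  for (k in levels(key)) {
    st <- man$structure[key == k]
    mi <- setdiff(c("WG", "TZ"), st)
    if (length(mi)) {
      row <- man[key == k, ][1, ]
      stop(sprintf("manifest incomplete: case '%s' rater '%s' lacks %s",
                   row$case_id, row$rater_id, paste(mi, collapse = ", ")),
           call. = FALSE)
    }
  }
  base <- dirname(normalizePath(manifest_path))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  absent <- !file.exists(paths)
  if (any(absent))
    stop(sprintf("mask file(s) not found: %s",
                 paste(utils::head(man$path[absent], 5), collapse = ", ")),
         call. = FALSE)
  man$path <- paths
  rg <- tapply(man$experience_group, man$rater_id, function(g) g[1])
  volumes <- NULL
  if (load_volumes) {
    volumes <- list()
    for (cid in unique(man$case_id)) {
      sub <- man[man$case_id == cid, ]
      vols <- list(WG = list(), TZ = list())
      ref_dim <- NULL
      for (i in seq_len(nrow(sub))) {
        v <- read_label_volume(sub$path[i])
        if (is.null(ref_dim)) ref_dim <- dim(v$voxels)
        if (!identical(dim(v$voxels), ref_dim))
          stop(sprintf("case '%s': mask shapes differ across raters (%s vs %s at %s)",
                       cid, paste(ref_dim, collapse = "x"),
                       paste(dim(v$voxels), collapse = "x"),
                       basename(sub$path[i])), call. = FALSE)
        vols[[sub$structure[i]]][[sub$rater_id[i]]] <- v
      }
      volumes[[as.character(cid)]] <- vols
    }
  }
  tab <- table(rg)
  message(sprintf("cohort: %d cases, %d raters (%s)",
                  length(unique(man$case_id)), length(rg),
                  paste(sprintf("%s %s", tab, names(tab)), collapse = ", ")))
  structure(list(manifest = man, rater_groups = rg, volumes = volumes),
            class = "rater_cohort")
}

#' @export
print.rater_cohort <- function(x, ...) {
  cat(sprintf("<rater_cohort> %d cases x %d raters, %s\n",
              length(unique(x$manifest$case_id)), length(x$rater_groups),
              if (is.null(x$volumes)) "volumes on disk" else "volumes in memory"))
  invisible(x)
}
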