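## ---- number formatting: full float precision round-trips -------------------
fmt_num <- function(x) sprintf("%.17g", x)

role_codes <- c(HIS = 0L, BRANCH = 1L, PVJ_STEM = 2L, PVJ = 3L)
fascicle_codes <- c(his = 0L, lv_sf = 1L, lv_af = 2L, lv_pf = 3L,
                    rv_sf = 4L, rv_mod = 5L)
tag_codes <- c(LV_ENDO = 1L, RV_ENDO = 2L, EPI = 3L, BASE = 4L)
region_codes <- c(LV_WALL = 1L, RV_WALL = 2L, SEPTUM = 3L)

xml_data_array <- function(name, values, type = "Float64", ncomp = 1) {
  paste0('<DataArray type="', type, '" Name="', name,
         '" NumberOfComponents="', ncomp, '" format="ascii">\n',
         paste(values, collapse = " "), "\n</DataArray>")
}

#' Write / read a biventricular mesh as VTK unstructured grid (.vtu)
#'
#' ASCII XML UnstructuredGrid holding the tetrahedra (cell type 10) followed
#' by the tagged boundary triangles (cell type 5). Per-node UVC values are
#' stored as four point-data arrays `z`, `rho`, `phi`, `nu` plus `d_endo`;
#' element regions and surface tags as integer cell arrays (`region` is -1
#' on triangles, `surface_tag` is -1 on tetrahedra). Round-trips preserve
#' coordinates to full float precision and topology exactly.
#'
#' @param mesh a `biv_mesh`; @param frame optional `uvc_frame` (adds UVC
#'   point data); @param path output file.
#' @return `write_vtu` returns `path` invisibly; `read_vtu` returns a list
#'   with `mesh` and (when UVC arrays are present) `frame`.
#' @export
write_vtu <- function(mesh, path, frame = NULL) {
  n <- nrow(mesh$nodes)
  tets <- mesh$elems
  tris <- mesh$surface$tri
  ncell <- nrow(tets) + nrow(tris)
  conn <- c(as.vector(t(tets)) - 1L, as.vector(t(tris)) - 1L)
  offs <- cumsum(c(rep(4L, nrow(tets)), rep(3L, nrow(tris))))
  types <- c(rep(10L, nrow(tets)), rep(5L, nrow(tris)))
  region <- c(region_codes[as.character(mesh$region)],
              rep(-1L, nrow(tris)))
  stag <- c(rep(-1L, nrow(tets)), tag_codes[as.character(mesh$surface$tag)])
  pd <- ""
  if (!is.null(frame)) {
    pd <- paste0("<PointData>\n",
                 xml_data_array("z", fmt_num(frame$uvc[, "z"])), "\n",
                 xml_data_array("rho", fmt_num(frame$uvc[, "rho"])), "\n",
                 xml_data_array("phi", fmt_num(frame$uvc[, "phi"])), "\n",
                 xml_data_array("nu", fmt_num(frame$uvc[, "nu"])), "\n",
                 xml_data_array("d_endo", fmt_num(frame$d_endo)), "\n",
                 "</PointData>\n")
  }
  txt <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    '<Piece NumberOfPoints="', n, '" NumberOfCells="', ncell, '">\n',
    "<Points>\n",
    xml_data_array("Points", fmt_num(as.vector(t(mesh$nodes))), ncomp = 3),
    "\n</Points>\n",
    pd,
    "<Cells>\n",
    xml_data_array("connectivity", conn, type = "Int64"), "\n",
    xml_data_array("offsets", offs, type = "Int64"), "\n",
    xml_data_array("types", types, type = "UInt8"), "\n",
    "</Cells>\n",
    "<CellData>\n",
    xml_data_array("region", region, type = "Int32"), "\n",
    xml_data_array("surface_tag", stag, type = "Int32"), "\n",
    "</CellData>\n",
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(txt, path)
  invisible(path)
}

read_array <- function(doc, name) {
  node <- xml2::xml_find_first(doc, paste0(".//*[@Name='", name, "']"))
  if (inherits(node, "xml_missing"))
    stop("read_vtu: missing DataArray '", name, "'")
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
}

#' @rdname write_vtu
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- matrix(read_array(doc, "Points"), ncol = 3, byrow = TRUE)
  conn <- as.integer(read_array(doc, "connectivity")) + 1L
  offs <- as.integer(read_array(doc, "offsets"))
  types <- as.integer(read_array(doc, "types"))
  region <- as.integer(read_array(doc, "region"))
  stag <- as.integer(read_array(doc, "surface_tag"))
  starts <- c(1L, offs[-length(offs)] + 1L)
  is_tet <- types == 10L
  tets <- t(vapply(which(is_tet), function(i)
    conn[starts[i]:offs[i]], integer(4)))
  tris <- t(vapply(which(!is_tet), function(i)
    conn[starts[i]:offs[i]], integer(3)))
  bf <- list(tri = tris)
  e1 <- pts[tris[, 2], , drop = FALSE] - pts[tris[, 1], , drop = FALSE]
  e2 <- pts[tris[, 3], , drop = FALSE] - pts[tris[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- row_norms(nrm)
  mesh <- structure(list(
    nodes = pts, elems = tets,
    region = factor(names(region_codes)[region[is_tet]],
                    levels = names(region_codes)),
    surface = list(tri = tris,
                   tag = factor(names(tag_codes)[stag[!is_tet]],
                                levels = names(tag_codes)),
                   normal = nrm / pmax(a2, .Machine$double.eps),
                   area = a2 / 2),
    params = NULL, internals = NULL), class = "biv_mesh")
  frame <- NULL
  zn <- xml2::xml_find_first(doc, ".//*[@Name='z']")
  if (!inherits(zn, "xml_missing")) {
    uvc <- cbind(z = read_array(doc, "z"), rho = read_array(doc, "rho"),
                 phi = read_array(doc, "phi"), nu = read_array(doc, "nu"))
    frame <- structure(list(nodes = pts, uvc = uvc,
                            d_endo = read_array(doc, "d_endo"),
                            edge_length = NA_real_,
                            arc_lv = NA_real_, arc_rv = NA_real_),
                       class = "uvc_frame")
  }
  list(mesh = mesh, frame = frame)
}

#' Write / read a mesh as a CARP-style text triplet
#'
#' `<base>.pts` (node count, then `x y z` per line), `<base>.elem`
#' (element count, then `Tt n1 n2 n3 n4 region` with 0-based node indices),
#' `<base>.lon` (one fibre vector per element; the synthetic mesh carries
#' no fibre architecture, so unit x vectors are written) and
#' `<base>.surf` (`Tr n1 n2 n3 tag`, 0-based).
#'
#' @param mesh a `biv_mesh`; @param base path prefix.
#' @return `write_carp` returns `base` invisibly; `read_carp` a `biv_mesh`.
#' @export
write_carp <- function(mesh, base) {
  pts <- c(nrow(mesh$nodes),
           paste(fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                 fmt_num(mesh$nodes[, 3])))
  writeLines(pts, paste0(base, ".pts"))
  el <- mesh$elems - 1L
  elem <- c(nrow(el),
            paste("Tt", el[, 1], el[, 2], el[, 3], el[, 4],
                  region_codes[as.character(mesh$region)]))
  writeLines(elem, paste0(base, ".elem"))
  writeLines(c(nrow(el), rep("1 0 0", nrow(el))), paste0(base, ".lon"))
  tr <- mesh$surface$tri - 1L
  surf <- c(nrow(tr),
            paste("Tr", tr[, 1], tr[, 2], tr[, 3],
                  tag_codes[as.character(mesh$surface$tag)]))
  writeLines(surf, paste0(base, ".surf"))
  invisible(base)
}

#' @rdname write_carp
#' @export
read_carp <- function(base) {
  pl <- readLines(paste0(base, ".pts"))
  n <- as.integer(pl[1])
  if (is.na(n) || length(pl) < n + 1) stop("read_carp: malformed .pts header")
  pts <- matrix(as.numeric(unlist(strsplit(pl[2:(n + 1)], "\\s+"))),
                ncol = 3, byrow = TRUE)
  el <- readLines(paste0(base, ".elem"))
  m <- as.integer(el[1])
  toks <- strsplit(el[2:(m + 1)], "\\s+")
  bad <- which(vapply(toks, function(t) t[1] != "Tt" || length(t) < 6,
                      logical(1)))
  if (length(bad))
    stop("read_carp: malformed .elem record at line ", bad[1] + 1)
  em <- matrix(as.integer(unlist(lapply(toks, `[`, 2:6))), ncol = 5,
               byrow = TRUE)
  sl <- readLines(paste0(base, ".surf"))
  s <- as.integer(sl[1])
  st <- strsplit(sl[2:(s + 1)], "\\s+")
  sm <- matrix(as.integer(unlist(lapply(st, `[`, 2:5))), ncol = 4,
               byrow = TRUE)
  tris <- sm[, 1:3, drop = FALSE] + 1L
  e1 <- pts[tris[, 2], , drop = FALSE] - pts[tris[, 1], , drop = FALSE]
  e2 <- pts[tris[, 3], , drop = FALSE] - pts[tris[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- row_norms(nrm)
  structure(list(
    nodes = pts,
    elems = em[, 1:4, drop = FALSE] + 1L,
    region = factor(names(region_codes)[em[, 5]],
                    levels = names(region_codes)),
    surface = list(tri = tris,
                   tag = factor(names(tag_codes)[sm[, 4]],
                                levels = names(tag_codes)),
                   normal = nrm / pmax(a2, .Machine$double.eps),
                   area = a2 / 2),
    params = NULL, internals = NULL), class = "biv_mesh")
}

#' Write / read a Purkinje network as VTK polydata (.vtp)
#'
#' ASCII XML PolyData: points with integer point-data arrays `role` and
#' `fascicle` (coded; see Details), one line cell per cable segment with
#' cell-data array `fascicle`. PVJ couplings are written alongside as
#' `<path>.pvj` (two 0-based columns: network node, tissue node).
#'
#' Role codes: HIS 0, BRANCH 1, PVJ_STEM 2, PVJ 3. Fascicle codes: his 0,
#' lv_sf 1, lv_af 2, lv_pf 3, rv_sf 4, rv_mod 5.
#'
#' @param net a `purkinje_network`; @param path output `.vtp` path.
#' @return `write_vtp` returns `path` invisibly; `read_vtp` a
#'   `purkinje_network` (couplings restored from `<path>.pvj` if present).
#' @export
write_vtp <- function(net, path) {
  ns <- nrow(net$segments)
  txt <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    "<PolyData>\n",
    '<Piece NumberOfPoints="', nrow(net$nodes), '" NumberOfLines="', ns,
    '">\n',
    "<Points>\n",
    xml_data_array("Points", fmt_num(as.vector(t(net$nodes))), ncomp = 3),
    "\n</Points>\n",
    "<PointData>\n",
    xml_data_array("role", role_codes[net$role], type = "Int32"), "\n",
    xml_data_array("fascicle", fascicle_codes[net$fascicle],
                   type = "Int32"), "\n",
    "</PointData>\n",
    "<Lines>\n",
    xml_data_array("connectivity",
                   as.vector(rbind(net$segments$from - 1L,
                                   net$segments$to - 1L)), type = "Int64"),
    "\n",
    xml_data_array("offsets", seq_len(ns) * 2L, type = "Int64"), "\n",
    "</Lines>\n",
    "<CellData>\n",
    xml_data_array("fascicle", fascicle_codes[net$segments$fascicle],
                   type = "Int32"), "\n",
    xml_data_array("length", fmt_num(net$segments$length)), "\n",
    "</CellData>\n",
    "</Piece>\n</PolyData>\n</VTKFile>\n")
  writeLines(txt, path)
  if (nrow(net$pvj))
    writeLines(paste(net$pvj$pvj - 1L, net$pvj$tissue - 1L),
               paste0(path, ".pvj"))
  invisible(path)
}

#' @rdname write_vtp
#' @export
read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  pts <- matrix(read_array(doc, "Points"), ncol = 3, byrow = TRUE)
  conn <- as.integer(read_array(doc, "connectivity")) + 1L
  from <- conn[seq(1, length(conn), by = 2)]
  to <- conn[seq(2, length(conn), by = 2)]
  fas_pt <- as.integer(read_array(doc, "fascicle"))
  ## the first 'fascicle' array is point data, the second cell data
  fas_all <- xml2::xml_find_all(doc, ".//*[@Name='fascicle']")
  fas_cell <- as.numeric(strsplit(trimws(xml2::xml_text(fas_all[[2]])),
                                  "\\s+")[[1]])
  lens <- read_array(doc, "length")
  pvj_path <- paste0(path, ".pvj")
  pvj <- if (file.exists(pvj_path)) {
    pv <- read.table(pvj_path)
    data.frame(pvj = pv[, 1] + 1L, tissue = pv[, 2] + 1L)
  } else data.frame(pvj = integer(0), tissue = integer(0))
  role <- names(role_codes)[as.integer(read_array(doc, "role")) + 1L]
  new_purkinje_network(
    nodes = pts,
    role = role,
    fascicle = names(fascicle_codes)[fas_pt + 1L],
    segments = data.frame(from = from, to = to, length = lens,
                          fascicle = names(fascicle_codes)[fas_cell + 1L],
                          stringsAsFactors = FALSE),
    pvj = pvj)
}

#' Write / read a Purkinje network in plain-text cable format
#'
#' `<base>.nodes`: node count, then `x y z role fascicle` per node;
#' `<base>.segs`: segment count, then `from to length fascicle` with
#' 0-based node indices.
#'
#' @param net a `purkinje_network`; @param base path prefix.
#' @return `write_cable` returns `base` invisibly; `read_cable` a
#'   `purkinje_network`.
#' @export
write_cable <- function(net, base) {
  writeLines(c(nrow(net$nodes),
               paste(fmt_num(net$nodes[, 1]), fmt_num(net$nodes[, 2]),
                     fmt_num(net$nodes[, 3]), net$role, net$fascicle)),
             paste0(base, ".nodes"))
  writeLines(c(nrow(net$segments),
               paste(net$segments$from - 1L, net$segments$to - 1L,
                     fmt_num(net$segments$length), net$segments$fascicle)),
             paste0(base, ".segs"))
  invisible(base)
}

#' @rdname write_cable
#' @export
read_cable <- function(base) {
  nl <- readLines(paste0(base, ".nodes"))
  n <- as.integer(nl[1])
  tok <- strsplit(nl[2:(n + 1)], "\\s+")
  pts <- matrix(as.numeric(unlist(lapply(tok, `[`, 1:3))), ncol = 3,
                byrow = TRUE)
  sl <- readLines(paste0(base, ".segs"))
  s <- as.integer(sl[1])
  st <- strsplit(sl[2:(s + 1)], "\\s+")
  new_purkinje_network(
    nodes = pts,
    role = vapply(tok, `[`, "", 4),
    fascicle = vapply(tok, `[`, "", 5),
    segments = data.frame(
      from = vapply(st, function(t) as.integer(t[1]), 1L) + 1L,
      to = vapply(st, function(t) as.integer(t[2]), 1L) + 1L,
      length = vapply(st, function(t) as.numeric(t[3]), 1),
      fascicle = vapply(st, `[`, "", 4), stringsAsFactors = FALSE))
}

#' Write / read an activation map as a one-value-per-line file
#'
#' CARP `.dat` convention: one activation time (ms) per mesh vertex;
#' unreached vertices are written as `-1`.
#'
#' @param act an `activation_map` (or numeric vector); @param path file.
#' @return `write_dat` returns `path` invisibly; `read_dat` a numeric
#'   vector with unreached entries restored to `Inf`.
#' @export
write_dat <- function(act, path) {
  v <- as.numeric(act)
  v[!is.finite(v)] <- -1
  writeLines(fmt_num(v), path)
  invisible(path)
}

#' @rdname write_dat
#' @export
read_dat <- function(path) {
  v <- as.numeric(readLines(path))
  v[v < 0] <- Inf
  v
}

#' Write / read a 12-lead ECG as CSV
#'
#' Time column (ms) plus one column per lead; a comment header line
#' carries the sample rate.
#'
#' @param ecg an `ecg12`; @param path file.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` an
#'   `ecg12`.
#' @export
write_ecg_csv <- function(ecg, path) {
  df <- data.frame(t = ecg$t, t(ecg$leads), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sample_rate_hz=", fmt_num(ecg$sample_rate)), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub("# sample_rate_hz=", "", hdr, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  leads <- t(as.matrix(df[, -1]))
  structure(list(leads = leads, t = df$t, sample_rate = fs,
                 lead_names = rownames(leads), log = character(0)),
            class = "ecg12")
}
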