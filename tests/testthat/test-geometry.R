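test_that("boundary triangles carry exactly one tag and partition the boundary", {
  g <- fix_geo()
  m <- g$mesh
  expect_false(any(is.na(m$surface$tag)))
  ## independent boundary extraction: faces referenced by exactly one tet
  faces <- rbind(m$elems[, c(1, 2, 3)], m$elems[, c(1, 2, 4)],
                 m$elems[, c(1, 3, 4)], m$elems[, c(2, 3, 4)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  cnt <- table(key)
  boundary_keys <- names(cnt)[cnt == 1]
  tagged_keys <- apply(m$surface$tri, 1, function(f)
    paste(sort(f), collapse = "-"))
  expect_setequal(tagged_keys, boundary_keys)
  expect_equal(anyDuplicated(tagged_keys), 0L)
  expect_setequal(as.character(unique(m$surface$tag)),
                  c("LV_ENDO", "RV_ENDO", "EPI", "BASE"))
})

test_that("mesh is a single connected component with positive volumes", {
  m <- fix_geo()$mesh
  ed <- rbind(m$elems[, c(1, 2)], m$elems[, c(1, 3)], m$elems[, c(1, 4)],
              m$elems[, c(2, 3)], m$elems[, c(2, 4)], m$elems[, c(3, 4)])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  vol <- hpstwin:::tet_signed_volume(m$nodes, m$elems)
  expect_true(all(vol > 0))
})

test_that("tetrahedron count agrees with a Delaunay re-tetrahedralization oracle", {
  ## frozen oracle: scipy.spatial.Delaunay on the LV-block node cloud,
  ## keeping tetrahedra whose centroid lies inside the analytic wall
  ## (offset-ellipsoid membership + polar-angle truncation) -> 15424 tets
  oracle_tets <- 15424
  m <- fix_geo()$mesh
  ours <- sum(m$region != "RV_WALL")
  expect_gt(ours / oracle_tets, 0.8)
  expect_lt(ours / oracle_tets, 1.2)
})

test_that("septal root coordinate lies on the RV-facing septal surface", {
  g <- fix_geo()
  b_rv_sf <- c(0.73, 1.0, -0.04, -1)
  r <- uvc_to_cartesian(g$frame, b_rv_sf)
  expect_lte(g$frame$d_endo[r$index], 0)
  expect_equal(unname(r$uvc["nu"]), -1)
  ## the node sits on an RV_ENDO-tagged triangle
  rv_nodes <- unique(as.vector(
    g$mesh$surface$tri[g$mesh$surface$tag == "RV_ENDO", ]))
  expect_true(r$index %in% rv_nodes)
})

test_that("analytic UVC is monotone along apex-base and endo-epi paths", {
  g <- fix_geo()
  f <- g$frame
  ## z strictly increases along the meridian at fixed phi/rho on the LV endo
  lv_endo <- which(f$uvc[, "rho"] == 0 & f$uvc[, "nu"] == -1 &
                     abs(f$uvc[, "phi"] - f$uvc[2, "phi"]) < 1e-9)
  zs <- sort(f$uvc[lv_endo, "z"])
  expect_true(all(diff(zs) > 0))
  ## rho strictly increases along an endo->epi ray (fixed z, phi on free wall)
  zs <- unique(f$uvc[, "z"])
  z_mid <- zs[which.min(abs(zs - 0.5))]
  pick <- which(f$uvc[, "z"] == z_mid &
                  abs(abs(f$uvc[, "phi"]) - pi) < 0.1 & f$uvc[, "nu"] == -1)
  expect_gt(length(pick), 1)
  ord <- order(f$uvc[pick, "rho"])
  radii <- sqrt(rowSums(f$nodes[pick, 1:2, drop = FALSE]^2))
  expect_true(all(diff(radii[ord]) > 0))
  ## apex point has z near 0
  apex <- which.min(f$nodes[, 3])
  expect_lte(f$uvc[apex, "z"], 0.05)
})

test_that("degenerate geometry parameters are rejected with diagnostics", {
  expect_error(geometry_params(lv_epi_radius = 19, lv_endo_radius = 20),
               "wall thickness")
  expect_error(geometry_params(rv_wall_thickness = -1), "positive")
  expect_error(geometry_params(edge_length = 9), "edge_length")
  expect_error(geometry_params(rv_sector_half_width = 4), "intersect")
})

test_that("surface_ray_pair recovers the wall thickness on the shells", {
  g <- fix_geo()
  m <- g$mesh
  f <- g$frame
  wall <- m$params$lv_epi_radius - m$params$lv_endo_radius
  tri <- m$surface$tri
  lv_nodes <- unique(as.vector(tri[m$surface$tag == "LV_ENDO", ]))
  ## free-wall LV endo points away from base/apex
  cand <- lv_nodes[abs(f$uvc[lv_nodes, "phi"]) > 2 &
                     f$uvc[lv_nodes, "z"] > 0.3 & f$uvc[lv_nodes, "z"] < 0.7]
  for (i in cand[seq(1, length(cand), length.out = 5)]) {
    rp <- surface_ray_pair(m, m$nodes[i, ], "LV_ENDO")
    expect_lt(abs(rp$distance - wall) / wall, 0.1)
  }
  ## septal-face rays never hit the originating surface (interior points,
  ## away from the attachment rims where the cavity normal degenerates)
  rv_nodes <- unique(as.vector(tri[m$surface$tag == "RV_ENDO", ]))
  sept <- rv_nodes[f$uvc[rv_nodes, "nu"] == -1 &
                     abs(f$uvc[rv_nodes, "phi"]) < 0.8 &
                     f$uvc[rv_nodes, "z"] > 0.4 & f$uvc[rv_nodes, "z"] < 0.8]
  for (i in sept[seq(1, length(sept), length.out = 5)]) {
    rp <- surface_ray_pair(m, m$nodes[i, ], "RV_ENDO")
    expect_true(rp$tag %in% c("LV_ENDO", "EPI"))
  }
})

test_that("ray-pair distances match an exhaustive all-triangle oracle", {
  g <- fix_geo()
  m <- g$mesh
  tri <- m$surface$tri
  tags <- as.character(m$surface$tag)
  ## independent Moeller-Trumbore in R
  ray_tri_r <- function(orig, dir, v0, v1, v2) {
    e1 <- v1 - v0; e2 <- v2 - v0
    p <- cross3_r(dir, e2)
    det <- sum(e1 * p)
    if (abs(det) < 1e-9) return(Inf)
    tv <- orig - v0
    u <- sum(tv * p) / det
    if (u < -1e-9 || u > 1 + 1e-9) return(Inf)
    q <- cross3_r(tv, e1)
    v <- sum(dir * q) / det
    if (v < -1e-9 || u + v > 1 + 1e-9) return(Inf)
    t <- sum(e2 * q) / det
    if (t < 1e-6) Inf else t
  }
  cross3_r <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])
  set.seed(99)
  lv_nodes <- unique(as.vector(tri[tags == "LV_ENDO", ]))
  pts <- sample(lv_nodes, 50)
  for (i in pts) {
    rp <- surface_ray_pair(m, m$nodes[i, ], "LV_ENDO")
    other <- which(tags != "LV_ENDO")
    ts <- vapply(other, function(k)
      ray_tri_r(m$nodes[i, ], rp$direction, m$nodes[tri[k, 1], ],
                m$nodes[tri[k, 2], ], m$nodes[tri[k, 3], ]), numeric(1))
    expect_equal(rp$distance, min(ts), tolerance = 1e-9)
  }
})
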