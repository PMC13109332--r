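zcloud <- function(z) {
  colored_point_cloud(cbind(seq_along(z), 0, z),
                      matrix(0.5, length(z), 3))
}

test_that("plant height equals the full-sort oracle", {
  expect_equal(estimate_plant_height(zcloud(1:100)), 98)
  expect_equal(estimate_plant_height(zcloud(rep(7.5, 40))), 7.5)
  expect_equal(estimate_plant_height(zcloud(1:10), top_fraction = 1),
               mean(1:10))
  set.seed(61)
  for (n in c(1, 7, 100, 1234)) {
    z <- rnorm(n, 100, 30)
    for (f in c(0.01, 0.05, 0.5, 1)) {
      n_top <- max(1, ceiling(f * n))
      oracle <- mean(sort(z, decreasing = TRUE)[seq_len(n_top)])
      expect_identical(estimate_plant_height(zcloud(z), top_fraction = f),
                       oracle)
    }
  }
  expect_equal(estimate_plant_height(zcloud(1:100), reference_z_mm = 10), 88)
  empty <- colored_point_cloud(matrix(numeric(0), 0, 3),
                               matrix(numeric(0), 0, 3))
  expect_error(estimate_plant_height(empty), class = "trayphen_empty_cloud")
  expect_error(estimate_plant_height(zcloud(1), top_fraction = 0),
               class = "trayphen_invalid_param")
})

test_that("projected canopy area counts occupied raster cells", {
  one <- colored_point_cloud(cbind(0.3, 0.7, 0), matrix(0.5, 1, 3))
  expect_equal(projected_canopy_area(one), 1)
  two <- colored_point_cloud(rbind(c(0.1, 0.1, 0), c(0.9, 0.9, 5)),
                             matrix(0.5, 2, 3))
  expect_equal(projected_canopy_area(two), 1)
  g <- as.matrix(expand.grid(x = 0:99 + 0.5, y = 0:99 + 0.5))
  grid_cloud <- colored_point_cloud(cbind(g, 0), matrix(0.5, 10000, 3))
  expect_equal(projected_canopy_area(grid_cloud), 10000)
  expect_equal(projected_canopy_area(grid_cloud, cell_mm = 10), 10000)
  empty <- colored_point_cloud(matrix(numeric(0), 0, 3),
                               matrix(numeric(0), 0, 3))
  expect_warning(a <- projected_canopy_area(empty), "empty")
  expect_equal(a, 0)
})

test_that("green pixel counting converts to physical area", {
  img_green <- array(rep(c(0, 1, 0), each = 100), c(10, 10, 3))
  expect_equal(green_pixel_area(img_green, mm_per_pixel = 1), 100)
  img_black <- array(0, c(10, 10, 3))
  expect_equal(green_pixel_area(img_black, mm_per_pixel = 1), 0)
  img <- array(0, c(100, 100, 3))
  img[seq_len(25), , 2] <- 1                      # 2500 green pixels
  expect_equal(green_pixel_area(img, mm_per_pixel = 0.5), 625)
  ## PNG path input goes through the same counting
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  expect_equal(green_pixel_area(path, mm_per_pixel = 0.5), 625)
  expect_error(green_pixel_area(img, mm_per_pixel = 0),
               class = "trayphen_invalid_param")
  expect_error(green_pixel_area(array(0, c(4, 4)), mm_per_pixel = 1),
               class = "trayphen_invalid_image")
})

test_that("cross-section slab membership is inclusive", {
  cl <- zcloud(c(150, 163, 167.9, 168.1))
  cs <- cross_section(cl, 163, 5)
  expect_setequal(cs$slab$points[, 3], c(163, 167.9))
  all_in <- cross_section(cl, 160, 1000)
  expect_identical(n_points(all_in$slab), 4L)
  none <- cross_section(cl, 500, 5)
  expect_identical(n_points(none$slab), 0L)
  expect_equal(none$area_mm2, 0)
})

test_that("bounding-box volume is the extent product", {
  cl <- colored_point_cloud(rbind(c(0, 0, 0), c(10, 20, 30)),
                            matrix(0.5, 2, 3))
  expect_equal(bbox_volume(cl), 6000)
  flat <- colored_point_cloud(cbind(runif(10), runif(10), 1),
                              matrix(0.5, 10, 3))
  expect_equal(bbox_volume(flat), 0)
  set.seed(62)
  cl <- rand_cloud(1000)
  expect_equal(bbox_volume(cl), prod(apply(cl$points, 2, function(v)
    diff(range(v)))))
})

test_that("voxel volume counts distinct occupied voxels", {
  one <- colored_point_cloud(cbind(1, 1, 1), matrix(0.5, 1, 3))
  expect_equal(voxel_volume(one, 5), 125)
  g <- as.matrix(expand.grid(x = 0:9, y = 0:9, z = 0:9)) * 5 + 2.5
  grid_cloud <- colored_point_cloud(g, matrix(0.5, 1000, 3))
  expect_equal(voxel_volume(grid_cloud, 5), 125000)
  pair <- colored_point_cloud(rbind(c(1, 1, 1), c(1.05, 1.05, 1.05)),
                              matrix(0.5, 2, 3))
  expect_equal(voxel_volume(pair, 5), 125)
  set.seed(63)
  cl <- rand_cloud(500, sd = 20)
  expect_lte(voxel_volume(cl, 5), 500 * 125)
  ## translation by exact voxel multiples leaves the volume unchanged
  shifted <- apply_similarity(cl, similarity_transform(translation = c(10, -15, 5)))
  expect_equal(voxel_volume(shifted, 5), voxel_volume(cl, 5))
})

test_that("mesh volume matches closed forms and scaling laws", {
  expect_equal(mesh_volume(cube_mesh()), 1)
  expect_equal(mesh_volume(tet_mesh()), 1 / 6)
  sphere <- icosphere_mesh(radius = 10, subdivisions = 3)
  expect_lt(abs(mesh_volume(sphere) - 4 * pi * 1000 / 3) / (4 * pi * 1000 / 3),
            0.01)
  ## rigid invariance and cubic scaling
  set.seed(64)
  r <- rand_rotation()
  moved <- triangle_mesh(sweep(cube_mesh()$vertices %*% t(r), 2,
                               c(5, -3, 2), "+"), cube_mesh()$faces)
  expect_equal(mesh_volume(moved), 1, tolerance = 1e-9)
  scaled <- triangle_mesh(cube_mesh()$vertices * 3, cube_mesh()$faces)
  expect_equal(mesh_volume(scaled), 27, tolerance = 1e-12)
})

test_that("defective meshes raise topology errors naming the bad edge", {
  open_mesh <- triangle_mesh(cube_mesh()$vertices, cube_mesh()$faces[-1, ])
  expect_error(mesh_volume(open_mesh), class = "trayphen_mesh_topology",
               regexp = "watertight")
  flipped <- cube_mesh()$faces
  flipped[1, ] <- rev(flipped[1, ])
  expect_error(mesh_volume(triangle_mesh(cube_mesh()$vertices, flipped)),
               class = "trayphen_mesh_topology")
  expect_error(triangle_mesh(cube_mesh()$vertices, matrix(99, 1, 3)),
               class = "trayphen_invalid_mesh")
})

test_that("voxel volume undercuts the bounding box on gappy canopies", {
  for (s in 1:3) {
    sim <- generate_scene(small_scene_config(seed = s))
    plant <- subset_cloud(sim$cloud, sim$ground_truth$labels == "plant")
    expect_lt(voxel_volume(plant, 5), bbox_volume(plant))
  }
})

test_that("image and point-cloud canopy areas agree on a rendered stand-in", {
  sim <- generate_scene(small_scene_config(seed = 7))
  plant <- subset_cloud(sim$cloud, sim$ground_truth$labels == "plant")
  cell <- 2
  idx <- floor(sweep(plant$points[, 1:2], 2,
                     c(min(plant$points[, 1]), min(plant$points[, 2]))) / cell)
  w <- max(idx[, 1]) + 1L; h <- max(idx[, 2]) + 1L
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 0.4; img[, , 3] <- 0.2            # soil-brown background
  img[cbind(idx[, 2] + 1L, idx[, 1] + 1L, 2L)] <- 1
  img[cbind(idx[, 2] + 1L, idx[, 1] + 1L, 1L)] <- 0
  area_img <- green_pixel_area(img, mm_per_pixel = cell)
  area_cloud <- projected_canopy_area(plant, cell_mm = cell)
  expect_lt(abs(area_img - area_cloud) / area_cloud, 0.1)
})

test_that("the phenotype report assembles every estimator", {
  sim <- generate_scene(small_scene_config(seed = 8))
  plant <- subset_cloud(sim$cloud, sim$ground_truth$labels == "plant")
  rep <- phenotype_report(plant, mesh = cube_mesh())
  expect_s3_class(rep, "phenotype_report")
  expect_equal(rep$height_mm, estimate_plant_height(plant))
  expect_equal(rep$canopy_cover_fraction, rep$canopy_area_mm2 / 180000)
  expect_equal(rep$mesh_volume_mm3, 1)
  expect_gt(rep$crosssection_area_mm2, 0)
  expect_lt(rep$voxel_volume_mm3, rep$bbox_volume_mm3)
})
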