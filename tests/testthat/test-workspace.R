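test_that("an empty workspace survives a save/load cycle", {
  f <- withr::local_tempfile(fileext = ".h5")
  ws <- workspace(meta = list(record_id = "empty"))
  save_workspace(ws, f)
  ws2 <- load_workspace(f)
  expect_length(ws2$tracks, 0)
  expect_length(ws2$fiducials, 0)
  expect_length(ws2$partitions$start, 0)
  expect_equal(ws2$meta$record_id, "empty")
})

test_that("a populated workspace round-trips with exact floats", {
  f <- withr::local_tempfile(fileext = ".h5")
  sim <- gen_ecg(ecg_sim_spec(duration = 10, seed = 4))
  r <- detect_rpeaks(sim$track)
  ws <- workspace(tracks = list(ecg = sim$track),
                  partitions = partition_set(c("a", "b"), c(0, 5), c(2, 7.5)),
                  epochs = epoch_grid(2, labels = c("Q1", NA)),
                  meta = list(record_id = "r1", creator = "tester"))
  ws <- ws_add_fiducials(ws, r, "ecg")
  ws <- ws_add_fiducials(ws, fiducial_series("T", t = r$t + 0.31,
                                             amplitude = r$amplitude * 0.3),
                         "ecg")
  save_workspace(ws, f)
  ws2 <- load_workspace(f)
  expect_identical(ws2$tracks$ecg$values, ws$tracks$ecg$values)
  expect_identical(ws2$tracks$ecg$fs, ws$tracks$ecg$fs)
  expect_identical(ws2$fiducials$R$t, ws$fiducials$R$t)
  expect_identical(ws2$fiducials$R$amplitude, ws$fiducials$R$amplitude)
  expect_identical(ws2$fiducials$T$t, ws$fiducials$T$t)
  expect_equal(attr(ws2$fiducials$R, "track"), "ecg")
  expect_identical(as.data.frame(ws2$partitions), as.data.frame(ws$partitions))
  expect_identical(ws2$epochs$labels, ws$epochs$labels)
  expect_identical(ws2$epochs$epoch_length, ws$epochs$epoch_length)
})

test_that("save/load is the identity over randomized workspaces", {
  for (seed in 1:25) {
    f <- tempfile(fileext = ".h5")
    ws <- random_workspace(seed)
    save_workspace(ws, f)
    ws2 <- load_workspace(f)
    for (nm in names(ws$tracks)) {
      expect_identical(ws2$tracks[[nm]]$values, ws$tracks[[nm]]$values)
      expect_identical(ws2$tracks[[nm]]$offset, ws$tracks[[nm]]$offset)
    }
    for (nm in names(ws$fiducials)) {
      expect_identical(ws2$fiducials[[nm]]$t, ws$fiducials[[nm]]$t)
      expect_identical(ws2$fiducials[[nm]]$sublabel, ws$fiducials[[nm]]$sublabel)
    }
    expect_identical(as.data.frame(ws2$partitions), as.data.frame(ws$partitions))
    expect_identical(is.null(ws2$epochs), is.null(ws$epochs))
    if (!is.null(ws$epochs))
      expect_identical(ws2$epochs$labels, ws$epochs$labels)
    file.remove(f)
  }
})

test_that("the file is readable by a generic HDF5 walker at the documented layout", {
  f <- withr::local_tempfile(fileext = ".h5")
  ws <- random_workspace(99)
  save_workspace(ws, f)
  # walk the schema with rhdf5 primitives only (no package loader involved)
  ls <- rhdf5::h5ls(f)
  expect_true(all(c("meta", "tracks", "annotations", "partitions") %in%
                    ls$name[ls$group == "/"]))
  nm <- names(ws$tracks)[1]
  vals <- rhdf5::h5read(f, paste0("tracks/", nm, "/values"))
  expect_identical(as.numeric(vals), ws$tracks[[nm]]$values)
  at <- rhdf5::h5readAttributes(f, paste0("tracks/", nm))
  expect_equal(as.numeric(at$fs), ws$tracks[[nm]]$fs)
  rhdf5::h5closeAll()
})

test_that("schema problems are reported by name", {
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5createGroup(f, "meta")
  rhdf5::h5closeAll()
  expect_error(load_workspace(f), "tracks")
  expect_error(load_workspace(tempfile()), "no such workspace")
})

test_that("files from a newer major schema are rejected", {
  f <- withr::local_tempfile(fileext = ".h5")
  ws <- workspace()
  save_workspace(ws, f)
  # forge a future version stamp
  fid <- rhdf5::H5Fopen(f)
  oid <- rhdf5::H5Oopen(fid, "meta")
  rhdf5::h5writeAttribute("2.0", oid, "schema_version")
  rhdf5::H5Oclose(oid); rhdf5::H5Fclose(fid)
  expect_error(load_workspace(f), "newer schema")
})
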