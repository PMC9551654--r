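.onLoad <- function(libname, pkgname) {
  register_interpolator("idw", function(cloud, grid, cfg = idw_config(), ...) {
    idw_raster(cloud, grid, cfg)
  })
}
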