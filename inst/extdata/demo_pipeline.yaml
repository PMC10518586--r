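# End-to-end demo configuration: synthetic bilayer with a thinned patch,
# hydrogen-bonded DDA aggregate and a spanning water wire; SAXS fit on a
# generated curve; order parameters from the packaged hyperfine table; AFM
# post-processing of a generated force curve and height map.
seed: 1
output_dir: membraneprobe_demo
stages:
  simulate:
    n_frames: 4
    lipids_per_leaflet: 64
    lateral_box: [10.0, 10.0]
    head_plane_offset: 1.85
    patch:
      center_xy: [5.0, 5.0]
      radius: 1.5
      head_plane_offset_inside: 1.35
    aggregate:
      n_dda: 8
      center_xy: [5.0, 5.0]
      lateral_sigma: 0.6
      carboxyl_pairing: 1.0
    water:
      slab_bounds: [2.3, 3.2]
      count: 120
      wire:
        n_waters: 8
        spacing: 0.3
        endpoints_z: [-1.1, 1.1]
  traj_analyze:
    thickness_cell: 0.5
  saxs_fit:
    q_min: 0.5
    q_max: 2.5
  epr: {}
  afm:
    modulus: 2.0e+7
    breakthrough: [200, 4.0]
    noise: 5
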