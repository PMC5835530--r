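# Demo pipeline configuration: a 23-subject synthetic cohort emulating the
# modelled study -- sparse planted couplings per seed side, stimulation
# conditions strengthening existing couplings (+0.35) and recruiting two
# stimulus-specific regions per seed side (0.75), and baseline connectivity
# falling with disease severity.  Matches demo_cohort_spec().
rng_seed: 20180228
cohort:
  n_subjects: 23
  coupled_left:
    Left-Cerebellum-Cortex: 0.5
    Left-Hippocampus: 0.5
    ctx-lh-inferiorparietal: 0.5
  coupled_right:
    Right-Pallidum: 0.5
    Right-Amygdala: 0.5
    ctx-rh-middletemporal: 0.5
  condition_effects:
    noisy:
      left:
        Left-Cerebellum-Cortex: 0.35
        Left-Hippocampus: 0.35
        ctx-lh-inferiorparietal: 0.35
        ctx-lh-superiorparietal: 0.75
        Left-Thalamus-Proper: 0.75
      right:
        Right-Pallidum: 0.35
        Right-Amygdala: 0.35
        ctx-rh-middletemporal: 0.35
        ctx-rh-inferiorparietal: 0.75
        Right-Thalamus-Proper: 0.75
    sinusoidal:
      left:
        Left-Cerebellum-Cortex: 0.35
        Left-Hippocampus: 0.35
        ctx-lh-inferiorparietal: 0.35
        ctx-lh-superiorfrontal: 0.75
        ctx-lh-postcentral: 0.75
      right:
        Right-Pallidum: 0.35
        Right-Amygdala: 0.35
        ctx-rh-middletemporal: 0.35
        ctx-rh-precentral: 0.75
        Right-Caudate: 0.75
  severity_slope: -0.35
selection_alpha: 0.05
connectivity_alpha: 0.05
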