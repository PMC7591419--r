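# Default configuration for renal cryoablation simulation.
# All physical constants are configurable working defaults for kidney
# tissue; adjust per study. Units are stated per key.

tissue:
  rho_tissue: 1050.0        # kg/m^3
  c_unfrozen: 3600.0        # J/(kg K)
  c_frozen: 1800.0          # J/(kg K)
  k_unfrozen: 0.52          # W/(m K)
  k_frozen: 2.0             # W/(m K)
  latent_heat: 250000.0     # J/kg
  T_liquidus: -1.0          # deg C (mushy-zone upper bound)
  T_solidus: -8.0           # deg C (mushy-zone lower bound)
  omega_perfusion: 0.004    # 1/s
  rho_blood: 1060.0         # kg/m^3
  c_blood: 3600.0           # J/(kg K)
  T_body: 37.0              # deg C

needle_defaults:
  iceseed_active_length_mm: 15.0   # IceSeed active tip
  icerod_active_length_mm: 25.0    # IceRod active tip
  radius_mm: 0.735                 # 17 G shaft radius

protocol:
  cycles: 2
  freeze_s: 600.0           # 10 min active freezing per cycle
  passive_s: 120.0          # 2 min passive thawing per cycle
  active_s: 60.0            # 1 min active thawing per cycle

solver:
  T_freeze_C: -140.0        # probe surface at full freezing power
  T_thaw_C: 20.0            # probe surface during active thaw
  safety: 0.9               # fraction of the explicit stability bound
  dt_s: auto                # or a fixed step in seconds

death:
  T_lethal_C: -20.0         # lethal isotherm
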