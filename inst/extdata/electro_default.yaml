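# Default electro-model configuration: H. pluvialis in basal medium,
# continuous-flow nsPEF treatment. Units stated per key.
radius_um: 14          # cell radius, micrometres
c_m_uF_cm2: 1          # specific membrane capacitance, uF/cm2
sigma_i_mS_cm: 10      # cytoplasm conductivity, mS/cm
sigma_e_mS_cm: 1.6     # medium conductivity, mS/cm
field_kV_cm: 40        # field strength, kV/cm
v_th_V: 1              # irreversible-electroporation threshold, V
durations_ns: [25, 50] # pulse durations, ns
freq_hz: 4             # pulse repetition frequency, Hz
flow_ml_min: 3.75      # pump flow rate, ml/min
chamber_ml: 0.5        # treatment-chamber volume, ml
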