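# Clinical passive range-of-motion test -> muscle mapping for a full-scale
# lower-limb model (86-muscle naming convention). Postures are package
# defaults in degrees -- the exam descriptions do not fix them numerically --
# and are meant to be overridden per laboratory protocol. Coordinates absent
# from a posture are held at zero.
tests:
- name: hip_flexion_test
  posture_deg: {hip_flexion: 120}
  muscles: [Glut_Max1, Glut_Max2, Glut_Max3, Glut_Med1, Glut_Med2, Glut_Med3]
- name: hip_extension_test
  posture_deg: {hip_flexion: -15}
  muscles: [Iliacus, Psoas]
- name: hip_abduction_knee_0
  posture_deg: {hip_adduction: -30}
  muscles: [Add_Mag2, Add_Mag3, Add_Long]
- name: hip_internal_rotation_supine
  posture_deg: {hip_rotation: 40}
  muscles: [Glut_Med1, Glut_Med2, Glut_Med3]
- name: knee_flexion_test
  posture_deg: {knee_flexion: 130}
  muscles: [Rectus_Fem, Vast_Int, Vast_Med, Vast_Lat]
- name: popliteal_angle_unilateral
  posture_deg: {hip_flexion: 90, knee_flexion: 10}
  muscles: [Semimembr, Semitend, Gracilis, Bic_Fem_lh, Bic_Fem_sh]
- name: popliteal_angle_bilateral
  posture_deg: {hip_flexion: 90, knee_flexion: 15}
  muscles: [Semimembr, Semitend, Gracilis, Bic_Fem_lh, Bic_Fem_sh]
- name: dorsiflexion_knee_0
  posture_deg: {knee_flexion: 0, ankle_flexion: 20}
  muscles: [Soleus, Gastroc_Lat, Gastroc_Med]
- name: dorsiflexion_knee_90
  posture_deg: {knee_flexion: 90, ankle_flexion: 25}
  muscles: [Soleus]
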