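animal_id,group,tumor_volume_mm3,vessel_voxels,trunk_length_mm
m01,Control,412.3,6120,44.8
m02,Control,388.9,5893,46.1
m03,Control,455.0,6477,43.9
m04,Control,401.7,6051,45.3
m05,Control,430.2,6302,44.0
m06,Control,395.5,5920,46.6
m07,Control,420.8,6210,45.0
m08,RAD,288.4,5714,45.8
m09,RAD,301.2,5630,44.2
m10,RAD,275.9,5811,46.0
m11,RAD,310.6,5598,43.7
m12,RAD,266.1,5702,45.1
m13,RAD,295.3,,44.9
m14,RAD,280.7,5755,45.5
m15,RAD+MFH,198.2,5421,44.6
m16,RAD+MFH,210.5,5388,45.9
m17,RAD+MFH,185.7,5502,44.1
m18,RAD+MFH,204.9,5349,45.2
m19,RAD+MFH,192.3,5460,
m20,RAD+MFH,207.4,5301,44.4
m21,RAD+MFH,189.8,5437,45.7
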