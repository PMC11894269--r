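# Intrarater reliability data: Monson-sphere radii (mm) fitted twice
# (sessions R1, R2) on 15 digitally scanned dentition models.
model_id,r1_mm,r2_mm
M01,71.421,70.571
M02,77.826,77.585
M03,72.482,73.004
M04,75.685,75.898
M05,88.282,87.047
M06,76.537,75.919
M07,76.635,76.325
M08,100.793,100.773
M09,115.798,115.992
M10,71.838,70.615
M11,70.570,73.120
M12,66.758,66.981
M13,72.310,69.706
M14,84.234,84.346
M15,99.077,96.170
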