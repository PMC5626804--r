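cohort,subject,condition,accuracy_pct
healthy,H1,MIcs-No adap.,59.4
healthy,H2,MIcs-No adap.,51.3
healthy,H3,MIcs-No adap.,75.2
healthy,H4,MIcs-No adap.,54.8
healthy,H5,MIcs-No adap.,94.5
healthy,H6,MIcs-No adap.,52.7
healthy,H7,MIcs-No adap.,48.9
healthy,H8,MIcs-No adap.,63.1
healthy,H9,MIcs-No adap.,64.6
healthy,H10,MIcs-No adap.,58.7
healthy,H11,MIcs-No adap.,76.1
healthy,H12,MIcs-No adap.,82.9
healthy,H13,MIcs-No adap.,68.3
healthy,H14,MIcs-No adap.,77.9
healthy,H15,MIcs-No adap.,75.4
healthy,H16,MIcs-No adap.,75
healthy,H1,MIcs-FBDSA,61.5
healthy,H2,MIcs-FBDSA,66.5
healthy,H3,MIcs-FBDSA,86.7
healthy,H4,MIcs-FBDSA,63.9
healthy,H5,MIcs-FBDSA,89.5
healthy,H6,MIcs-FBDSA,54.5
healthy,H7,MIcs-FBDSA,57.3
healthy,H8,MIcs-FBDSA,64.3
healthy,H9,MIcs-FBDSA,60.9
healthy,H10,MIcs-FBDSA,63.2
healthy,H11,MIcs-FBDSA,76.4
healthy,H12,MIcs-FBDSA,76.4
healthy,H13,MIcs-FBDSA,75.4
healthy,H14,MIcs-FBDSA,77.7
healthy,H15,MIcs-FBDSA,80
healthy,H16,MIcs-FBDSA,74.5
healthy,H1,PMcs-No adap.,63.6
healthy,H2,PMcs-No adap.,54.6
healthy,H3,PMcs-No adap.,51.3
healthy,H4,PMcs-No adap.,57.0
healthy,H5,PMcs-No adap.,92.8
healthy,H6,PMcs-No adap.,62.9
healthy,H7,PMcs-No adap.,51.0
healthy,H8,PMcs-No adap.,54.4
healthy,H9,PMcs-No adap.,58.3
healthy,H10,PMcs-No adap.,50
healthy,H11,PMcs-No adap.,80.3
healthy,H12,PMcs-No adap.,74.2
healthy,H13,PMcs-No adap.,75.8
healthy,H14,PMcs-No adap.,66.2
healthy,H15,PMcs-No adap.,73.7
healthy,H16,PMcs-No adap.,75.8
healthy,H1,PMcs-FBDSA,67.9
healthy,H2,PMcs-FBDSA,56.9
healthy,H3,PMcs-FBDSA,73.8
healthy,H4,PMcs-FBDSA,68.3
healthy,H5,PMcs-FBDSA,90.4
healthy,H6,PMcs-FBDSA,65.4
healthy,H7,PMcs-FBDSA,58.2
healthy,H8,PMcs-FBDSA,59.3
healthy,H9,PMcs-FBDSA,59.5
healthy,H10,PMcs-FBDSA,58.2
healthy,H11,PMcs-FBDSA,77.3
healthy,H12,PMcs-FBDSA,81.8
healthy,H13,PMcs-FBDSA,75.9
healthy,H14,PMcs-FBDSA,74.5
healthy,H15,PMcs-FBDSA,75.5
healthy,H16,PMcs-FBDSA,73.6
stroke,A006,MIcs-No adap.,81.9
stroke,A018,MIcs-No adap.,65
stroke,A019,MIcs-No adap.,64.4
stroke,A024,MIcs-No adap.,57.5
stroke,A028,MIcs-No adap.,85.6
stroke,A031,MIcs-No adap.,90.6
stroke,A006,MIcs-FBDSA,85.7
stroke,A018,MIcs-FBDSA,69.3
stroke,A019,MIcs-FBDSA,86.4
stroke,A024,MIcs-FBDSA,67.1
stroke,A028,MIcs-FBDSA,85.7
stroke,A031,MIcs-FBDSA,87.1
stroke,A006,PMcs-No adap.,85.6
stroke,A018,PMcs-No adap.,55
stroke,A019,PMcs-No adap.,51.3
stroke,A024,PMcs-No adap.,55.6
stroke,A028,PMcs-No adap.,61.3
stroke,A031,PMcs-No adap.,93.8
stroke,A006,PMcs-FBDSA,84.3
stroke,A018,PMcs-FBDSA,67.9
stroke,A019,PMcs-FBDSA,80
stroke,A024,PMcs-FBDSA,59.3
stroke,A028,PMcs-FBDSA,87.86
stroke,A031,PMcs-FBDSA,92.86
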