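"","state1","state2","state3","state4","state5","state6","state7","state8","state9","state10","state11","state12","state13","state14","state15","state16","state17","state18","state19","state20","state21","state22","state23","state24","state25","state26","state27","state28","state29","state30","state31","state32"
"c1",1,1,10,15,15,8,7,7,4,11,11,1,14,11,1,14,24,15,17,20,10,14,16,16,25,24,27,3,20,5,3,7
"theta1",4,4,3,3,3,3,7,7,1,2,2,4,2,2,4,2,4,3,4,7,3,2,3,3,2,4,4,3,7,4,3,7
"c2",,3,29,16,16,13,,17,10,20,16,16,17,29,15,24,27,17,32,,20,16,17,17,26,26,32,19,31,31,31,17
"theta2",,3,4,3,3,1,,4,3,7,3,3,4,4,3,4,4,4,1,,7,3,4,4,4,4,1,3,3,3,3,4
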