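config,adduction_mean,adduction_min,adduction_max,er1_mean,er1_min,er1_max,ir1_mean,ir1_min,ir1_max,inferior_mean,inferior_min,inferior_max,anteroinferior_mean,anteroinferior_min,anteroinferior_max,posteroinferior_mean,posteroinferior_min,posteroinferior_max
36+0,-16.5,-35,5,32.4,0,125,28.2,0,100,2419.9,1349.2,4091.6,1444.9,342.5,2260.7,973.6,89.4,1957
36+2,-9.3,-30,15,64.6,0,135,55.9,0,130,2855.6,1580.5,4451.8,1713.0,435.5,2369.9,1138.7,299,2126.3
36+5,-9.1,-20,5,55.9,0,135,48.2,0,100,3465.6,2589.5,4552.1,1866.4,1301.7,2408.9,1597.6,946.8,2189.9
36+7,-6.3,-20,10,70.4,0,130,54.7,0,105,3980.7,3264.8,4797.5,2078.2,1762.7,2507.4,1899.5,1402.4,2326.8
42+0,-5.1,-25,15,77.2,0,150,67.6,0,140,5453.5,3907.7,7527.3,3102.0,1636.2,4143.3,2346.6,1075.6,3652.6
42+7,-0.7,-15,10,94.1,45,145,74.7,15,120,6850.0,5497.7,7961,3619.0,2759.7,4352.6,3225.5,2218.7,3826.1
42+10,1.8,-15,10,101.0,55,145,77.5,20,125,7606.3,6518.6,8505.8,3923.8,3416.5,4494.5,3678.3,2929.7,4175.6
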