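country,transform,model,coda_rmse,coda_mape
china,LCC.Y,ARIMA,0.09,6.10
china,LCC.Y,ETS,0.09,6.10
china,LCC.Y,VAR,0.17,11.48
china,LCC.Y,NNETTS,0.14,9.73
china,LCC.M,ARIMA,0.07,4.87
china,LCC.M,ETS,0.09,6.17
china,LCC.M,VAR,0.17,11.48
china,LCC.M,NNETTS,0.06,3.94
china,LCC.O,ARIMA,0.09,6.24
china,LCC.O,ETS,0.09,6.17
china,LCC.O,VAR,0.17,11.48
china,LCC.O,NNETTS,0.13,8.67
china,ILR,ARIMA,0.06,3.94
china,ILR,ETS,0.08,5.38
china,ILR,VAR,0.10,6.61
china,ILR,NNETTS,0.08,5.50
china,DRHT,ARIMA,0.08,5.67
china,DRHT,ETS,0.08,5.67
china,DRHT,VAR,0.10,6.91
china,DRHT,NNETTS,0.06,4.21
china,Base,ARIMA,0.08,5.10
china,Base,ETS,0.09,6.09
china,Base,VAR,0.17,11.48
china,Base,NNETTS,0.15,10.22
india,LCC.Y,ARIMA,0.02,1.06
india,LCC.Y,ETS,0.01,0.83
india,LCC.Y,VAR,0.02,1.11
india,LCC.Y,NNETTS,0.07,4.06
india,LCC.M,ARIMA,0.02,1.09
india,LCC.M,ETS,0.01,0.83
india,LCC.M,VAR,0.02,1.11
india,LCC.M,NNETTS,0.10,5.64
india,LCC.O,ARIMA,0.02,1.28
india,LCC.O,ETS,0.01,0.84
india,LCC.O,VAR,0.02,1.11
india,LCC.O,NNETTS,0.26,14.78
india,ILR,ARIMA,0.02,1.09
india,ILR,ETS,0.01,0.81
india,ILR,VAR,0.03,1.61
india,ILR,NNETTS,0.02,0.93
india,DRHT,ARIMA,0.02,1.07
india,DRHT,ETS,0.01,0.81
india,DRHT,VAR,0.02,1.11
india,DRHT,NNETTS,0.28,15.33
india,Base,ARIMA,0.02,1.09
india,Base,ETS,0.02,0.90
india,Base,VAR,0.02,1.11
india,Base,NNETTS,0.08,4.81
vietnam,LCC.Y,ARIMA,0.10,6.16
vietnam,LCC.Y,ETS,0.08,5.00
vietnam,LCC.Y,VAR,0.07,4.35
vietnam,LCC.Y,NNETTS,0.06,3.43
vietnam,LCC.M,ARIMA,0.10,6.11
vietnam,LCC.M,ETS,0.08,5.00
vietnam,LCC.M,VAR,0.07,4.35
vietnam,LCC.M,NNETTS,0.17,10.22
vietnam,LCC.O,ARIMA,0.10,6.05
vietnam,LCC.O,ETS,0.08,4.99
vietnam,LCC.O,VAR,0.07,4.35
vietnam,LCC.O,NNETTS,0.62,37.12
vietnam,ILR,ARIMA,0.08,4.64
vietnam,ILR,ETS,0.07,4.14
vietnam,ILR,VAR,0.07,4.41
vietnam,ILR,NNETTS,0.24,14.33
vietnam,DRHT,ARIMA,0.09,5.69
vietnam,DRHT,ETS,0.07,4.49
vietnam,DRHT,VAR,0.07,4.27
vietnam,DRHT,NNETTS,0.44,26.37
vietnam,Base,ARIMA,0.10,6.12
vietnam,Base,ETS,0.07,4.10
vietnam,Base,VAR,0.07,4.35
vietnam,Base,NNETTS,0.07,4.51
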